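#' Computational model of the slit-scan spectrometer
#'
#' Captures the imaging chain (slit, grating/prism dispersion, Bayer colour
#' filters, CMOS sensor) as a forward model: a ground-truth dispersion
#' polynomial, per-channel spectral sensitivity curves, sensor geometry,
#' a slit point-spread blur along the spatial axis, and a noise/quantization
#' model. Defaults follow a 1920 x 1080 consumer camera; tests use smaller
#' sensors.
#'
#' @param dispersion ground-truth `dispersion_model` (default: affine,
#'   400 nm + 0.39 nm/column, i.e. ~900 columns spanning 400-750 nm).
#' @param sensor_rows,sensor_cols sensor geometry (rows = spatial/slit axis,
#'   columns = spectral axis).
#' @param channel_response list of three functions of wavelength (R, G, B
#'   sensitivities in `[0, 1]`).
#' @param read_noise_sigma Gaussian read noise, DN.
#' @param shot_noise_scale signal-scaled noise: sd = scale * sqrt(signal DN).
#' @param bit_depth ADC bits, one of 8, 10, 12, 16.
#' @param slit_psf_sigma_px Gaussian blur sigma along the slit (spatial)
#'   axis, pixels; 0 disables blur.
#' @param iso_jitter_sd per-frame multiplicative gain jitter sd (models
#'   auto-ISO); 0 (default) disables it.
#' @return an object of class `instrument_model`.
#' @export
instrument_model <- function(dispersion = NULL,
                             sensor_rows = 1080, sensor_cols = 1920,
                             channel_response = default_channel_response(),
                             read_noise_sigma = 2,
                             shot_noise_scale = 0.5,
                             bit_depth = 8,
                             slit_psf_sigma_px = 0,
                             iso_jitter_sd = 0) {
  if (is.null(dispersion))
    dispersion <- dispersion_model(c(400, 0.39), c(1, min(sensor_cols, 898)))
  stopifnot(inherits(dispersion, "dispersion_model"))
  if (sensor_rows < 1 || sensor_cols < 1)
    stop("instrument_model: sensor dimensions must be positive")
  if (!bit_depth %in% c(8, 10, 12, 16))
    stop("instrument_model: bit_depth must be one of 8, 10, 12, 16")
  if (!is.list(channel_response) || length(channel_response) != 3L)
    stop("instrument_model: channel_response must be a list of 3 functions")
  if (read_noise_sigma < 0 || shot_noise_scale < 0 || slit_psf_sigma_px < 0 ||
      iso_jitter_sd < 0)
    stop("instrument_model: noise and blur parameters must be non-negative")
  structure(list(dispersion = dispersion,
                 sensor_rows = as.integer(sensor_rows),
                 sensor_cols = as.integer(sensor_cols),
                 channel_response = channel_response,
                 read_noise_sigma = read_noise_sigma,
                 shot_noise_scale = shot_noise_scale,
                 bit_depth = as.integer(bit_depth),
                 slit_psf_sigma_px = slit_psf_sigma_px,
                 iso_jitter_sd = iso_jitter_sd),
            class = "instrument_model")
}

#' Default RGB channel sensitivities
#'
#' Blue and green channels as Gaussians; the red channel as a sigmoid
#' plateau extending to 750 nm, the behaviour of a CMOS sensor whose
#' infrared-cut filter has been removed so the instrument reaches the
#' 740-750 nm vegetation band.
#'
#' @return list of three functions of wavelength (R, G, B).
#' @export
default_channel_response <- function() {
  list(
    R = function(wl) 0.92 * .sigmoid((wl - 590) / 12) * .sigmoid(-(wl - 765) / 18),
    G = function(wl) 0.95 * exp(-(wl - 535)^2 / (2 * 45^2)),
    B = function(wl) 1.00 * exp(-(wl - 460)^2 / (2 * 40^2))
  )
}

#' Summed (panchromatic) channel sensitivity
#'
#' @param model an `instrument_model`.
#' @return function of wavelength: R + G + B sensitivity.
#' @export
total_channel_response <- function(model) {
  stopifnot(inherits(model, "instrument_model"))
  cr <- model$channel_response
  function(wl) cr[[1]](wl) + cr[[2]](wl) + cr[[3]](wl)
}

#' Render one noiseless line spectrum
#'
#' The noiseless per-column, per-channel sensor signal for a single slit
#' position viewing one material:
#' `signal(col, ch) = illuminant(lambda(col)) * reflectance(lambda(col)) *
#' channel_response_ch(lambda(col))`, with `lambda` the model's dispersion.
#' Columns whose wavelength falls outside the material's grid contribute
#' zero (reflectance spectra evaluate to 0 there).
#'
#' @param material a `reflectance_spectrum`.
#' @param illuminant illuminant spectrum (function, `emission_lines`, or
#'   scalar; see [eval_spectrum()]).
#' @param model an `instrument_model`.
#' @return matrix `sensor_cols x 3` of noiseless signal, plus attribute
#'   `wavelength_nm` giving lambda(col) (NA outside the calibrated range).
#' @export
render_line_spectrum <- function(material, illuminant, model) {
  stopifnot(inherits(model, "instrument_model"))
  cols <- seq_len(model$sensor_cols)
  disp <- model$dispersion
  inside <- cols >= disp$col_range[1] & cols <= disp$col_range[2]
  wl <- rep(NA_real_, length(cols))
  wl[inside] <- wavelength_at(disp, cols[inside])
  if (!any(inside))
    stop("render_line_spectrum: dispersion covers no sensor column")
  if (inherits(material, "reflectance_spectrum") &&
      (max(material$wavelength_nm) < min(wl[inside]) ||
       min(material$wavelength_nm) > max(wl[inside])))
    stop("render_line_spectrum: material grid does not overlap the sensed range")
  refl <- numeric(length(cols))
  refl[inside] <- eval_spectrum(material, wl[inside])
  illu <- numeric(length(cols))
  illu[inside] <- eval_spectrum(illuminant, wl[inside])
  if (any(illu[inside] < 0))
    stop("render_line_spectrum: illuminant must be non-negative")
  radiance <- illu * refl
  out <- matrix(0, nrow = length(cols), ncol = 3,
                dimnames = list(NULL, c("R", "G", "B")))
  for (ch in 1:3) {
    r <- numeric(length(cols))
    r[inside] <- model$channel_response[[ch]](wl[inside])
    if (any(r < 0)) stop("render_line_spectrum: channel response must be non-negative")
    out[, ch] <- radiance * r
  }
  attr(out, "wavelength_nm") <- wl
  out
}

#' Map of materials across a push-broom scan
#'
#' Assigns a material label from a spectral library to every
#' (scan line, slit row) position, under a common illuminant.
#'
#' @param labels character matrix `n_scan_lines x slit_rows` of material
#'   labels; every label must exist in `library`.
#' @param library named list of `reflectance_spectrum` objects.
#' @param illuminant illuminant spectrum (see [eval_spectrum()]).
#' @return an object of class `scene_map`.
#' @export
scene_map <- function(labels, library, illuminant = flat_illuminant()) {
  labels <- as.matrix(labels)
  if (!all(labels %in% names(library)))
    stop("scene_map: undefined material label(s): ",
         paste(setdiff(unique(as.vector(labels)), names(library)), collapse = ", "))
  structure(list(labels = labels, library = library, illuminant = illuminant,
                 n_scan_lines = nrow(labels), slit_rows = ncol(labels)),
            class = "scene_map")
}

#' Simulate a push-broom scan
#'
#' Renders one dispersed colour frame per scan line: the noiseless signal of
#' each slit row's material, optionally blurred along the slit axis by a
#' Gaussian slit PSF, with Gaussian read noise and signal-scaled shot noise
#' added, then quantized (round half up) to the sensor bit depth. The
#' ground-truth hypercube holds the noiseless, unblurred panchromatic
#' (R+G+B) signal on the native wavelength axis.
#'
#' @param scene a `scene_map`; its `slit_rows` must equal the model's
#'   `sensor_rows`.
#' @param model an `instrument_model`.
#' @param seed integer seed; identical seeds give bit-identical frames.
#' @return list of class `scan_result`: `frames` (list of
#'   `rows x cols x 3` integer arrays), `truth` (ground-truth `hypercube`),
#'   `model`, `seed`.
#' @export
render_scan <- function(scene, model, seed) {
  stopifnot(inherits(scene, "scene_map"), inherits(model, "instrument_model"))
  if (missing(seed)) stop("render_scan: a seed is required")
  if (scene$slit_rows != model$sensor_rows)
    stop("render_scan: scene has ", scene$slit_rows,
         " slit rows but the sensor has ", model$sensor_rows)

  # per-material line spectra are shared across the scan
  mats <- unique(as.vector(scene$labels))
  line_by_mat <- lapply(mats, function(m)
    render_line_spectrum(scene$library[[m]], scene$illuminant, model))
  names(line_by_mat) <- mats
  wl <- attr(line_by_mat[[1]], "wavelength_nm")
  inside <- !is.na(wl)
  wl_axis <- wl[inside]
  flip <- is.unsorted(wl_axis)   # dispersion may run red-to-blue
  ord <- if (flip) rev(seq_along(wl_axis)) else seq_along(wl_axis)

  maxdn <- 2^model$bit_depth - 1
  n <- scene$n_scan_lines
  truth <- array(0, dim = c(n, model$sensor_rows, length(wl_axis)))
  frames <- vector("list", n)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  for (f in seq_len(n)) {
    noiseless <- array(0, dim = c(model$sensor_rows, model$sensor_cols, 3))
    pan <- matrix(0, model$sensor_rows, length(wl_axis))
    for (m in mats) {
      rows <- which(scene$labels[f, ] == m)
      if (!length(rows)) next
      sig <- line_by_mat[[m]]
      for (ch in 1:3) noiseless[rows, , ch] <-
          matrix(sig[, ch], length(rows), model$sensor_cols, byrow = TRUE)
      pan[rows, ] <- matrix(rowSums(sig)[inside][ord],
                            length(rows), length(wl_axis), byrow = TRUE)
    }
    truth[f, , ] <- pan
    x <- noiseless
    if (model$slit_psf_sigma_px > 0)
      for (ch in 1:3) x[, , ch] <- .gauss_blur_rows(x[, , ch], model$slit_psf_sigma_px)
    if (model$iso_jitter_sd > 0)
      x <- x * exp(stats::rnorm(1, 0, model$iso_jitter_sd))
    if (model$read_noise_sigma > 0 || model$shot_noise_scale > 0) {
      nel <- length(x)
      x <- x + stats::rnorm(nel, 0, model$read_noise_sigma) +
        stats::rnorm(nel, 0, 1) * model$shot_noise_scale * sqrt(pmax(x, 0))
    }
    frames[[f]] <- array(as.integer(pmin(pmax(floor(x + 0.5), 0), maxdn)),
                         dim = dim(x))
  }
  truth_cube <- hypercube(truth, wl_axis[ord],
                          provenance = list(source = "render_scan", seed = seed))
  structure(list(frames = frames, truth = truth_cube, model = model,
                 seed = as.integer(seed)),
            class = "scan_result")
}

# Gaussian blur down the rows (spatial/slit axis) of a matrix, kernel
# renormalized at the edges
.gauss_blur_rows <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  wsum <- numeric(n)
  for (j in seq_along(k)) {
    off <- j - half - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + k[j] * m[src[ok], , drop = FALSE]
    wsum[ok] <- wsum[ok] + k[j]
  }
  out / wsum
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.instrument_model <- function(x, ...) {
  cat("Instrument model: ", x$sensor_rows, " x ", x$sensor_cols,
      " sensor, ", x$bit_depth, "-bit\n", sep = "")
  cat("  dispersion ", format(x$dispersion$wavelength_range[1], digits = 6),
      "-", format(x$dispersion$wavelength_range[2], digits = 6),
      " nm over columns ", x$dispersion$col_range[1], "-",
      x$dispersion$col_range[2], "\n", sep = "")
  cat("  read noise", x$read_noise_sigma, "DN, shot scale",
      x$shot_noise_scale, ", slit PSF sigma", x$slit_psf_sigma_px, "px\n")
  invisible(x)
}

#' @export
print.scene_map <- function(x, ...) {
  cat("Scene map:", x$n_scan_lines, "scan lines x", x$slit_rows, "slit rows;",
      "materials:", paste(sort(unique(as.vector(x$labels))), collapse = ", "), "\n")
  invisible(x)
}
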