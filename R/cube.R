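#' Hyperspectral data cube
#'
#' The central product of push-broom reconstruction: a
#' `scan_lines x slit_rows x n_bands` intensity array with an explicit,
#' strictly increasing wavelength axis. Bands with no contributing sensor
#' column are marked invalid (and hold `NA`).
#'
#' @param data numeric array `scan_lines x slit_rows x n_bands`.
#' @param wavelength_nm band-centre wavelengths, strictly increasing,
#'   length `n_bands`.
#' @param valid logical per-band validity (default: bands free of `NA`).
#' @param provenance free-form list (calibration id, frame manifest, seed).
#' @return an object of class `hypercube`.
#' @export
hypercube <- function(data, wavelength_nm, valid = NULL, provenance = list()) {
  if (length(dim(data)) != 3L)
    stop("hypercube: data must be a 3-D array (scan x row x band)")
  wavelength_nm <- as.numeric(wavelength_nm)
  if (length(wavelength_nm) != dim(data)[3])
    stop("hypercube: wavelength axis length must equal the band count")
  if (any(diff(wavelength_nm) <= 0))
    stop("hypercube: wavelength axis must be strictly increasing")
  if (any(data < 0, na.rm = TRUE))
    stop("hypercube: negative intensities are not allowed")
  if (is.null(valid)) valid <- apply(!is.na(data), 3, all)
  structure(list(data = data, wavelength_nm = wavelength_nm,
                 valid = as.logical(valid), provenance = provenance),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat("Hypercube: ", d[1], " scan lines x ", d[2], " slit rows x ", d[3],
      " bands (", format(min(x$wavelength_nm), digits = 6), "-",
      format(max(x$wavelength_nm), digits = 6), " nm), ",
      sum(x$valid), " valid bands\n", sep = "")
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Uniform band-edge grid
#'
#' @param lo_nm,hi_nm wavelength limits of the grid.
#' @param n_bands number of bands; edges have length `n_bands + 1`.
#' @return numeric vector of band edges.
#' @export
uniform_band_edges <- function(lo_nm, hi_nm, n_bands) {
  if (lo_nm >= hi_nm || n_bands < 1) stop("uniform_band_edges: bad grid request")
  seq(lo_nm, hi_nm, length.out = n_bands + 1)
}

#' Native band edges of a dispersion model
#'
#' One band per detector column at the model's own sampling: edges are the
#' midpoints between consecutive column wavelengths, extended half a step at
#' both ends. This reproduces the native ~0.39 nm/column sampling
#' (about 900 bands over 400-750 nm).
#'
#' @param calib a `dispersion_model`.
#' @return numeric vector of band edges.
#' @export
native_band_edges <- function(calib) {
  stopifnot(inherits(calib, "dispersion_model"))
  cols <- seq(ceiling(calib$col_range[1]), floor(calib$col_range[2]))
  wl <- sort(wavelength_at(calib, cols))
  mid <- (wl[-1] + wl[-length(wl)]) / 2
  c(2 * wl[1] - mid[1], mid, 2 * wl[length(wl)] - mid[length(mid)])
}

#' Reduce one dispersed frame to a (slit row x band) line
#'
#' The gray value of each pixel is the unweighted channel sum R+G+B; each
#' detector column is assigned to the band whose half-open interval
#' `[edge_i, edge_{i+1})` contains its calibrated wavelength, and each
#' band's value is the mean over its contributing columns. Bands with no
#' contributing column are `NA` (invalid).
#'
#' @param frame `rows x cols x 3` numeric array (one slit exposure).
#' @param calib a `dispersion_model` valid over (part of) the frame columns.
#' @param band_edges ascending band-edge vector, within the calibrated
#'   wavelength range.
#' @return matrix `slit_rows x n_bands`, attribute `wavelength_nm` = band
#'   centres.
#' @export
frame_to_line <- function(frame, calib, band_edges) {
  stopifnot(inherits(calib, "dispersion_model"))
  d <- dim(frame)
  if (length(d) != 3L || d[3] != 3L)
    stop("frame_to_line: frame must be rows x cols x 3")
  band_edges <- as.numeric(band_edges)
  if (any(diff(band_edges) <= 0) || length(band_edges) < 2L)
    stop("frame_to_line: band_edges must be ascending, length >= 2")
  wr <- calib$wavelength_range
  # outermost edges may overhang by up to one band width; band centres must
  # stay inside the calibrated range
  slack <- stats::median(diff(band_edges))
  if (band_edges[1] < wr[1] - slack - 1e-9 ||
      band_edges[length(band_edges)] > wr[2] + slack + 1e-9)
    stop("frame_to_line: band grid extends outside the calibrated range (",
         format(wr[1]), "-", format(wr[2]), " nm)")
  cols <- seq_len(d[2])
  inside <- cols >= calib$col_range[1] & cols <= calib$col_range[2]
  if (!any(inside)) stop("frame_to_line: calibration covers no frame column")
  wl <- wavelength_at(calib, cols[inside])
  gray <- frame[, , 1] + frame[, , 2] + frame[, , 3]
  gray <- gray[, inside, drop = FALSE]

  n_bands <- length(band_edges) - 1L
  idx <- findInterval(wl, band_edges, rightmost.closed = FALSE)
  use <- idx >= 1L & idx <= n_bands & wl < band_edges[n_bands + 1L]
  out <- matrix(NA_real_, d[1], n_bands)
  if (any(use)) {
    # column -> band incidence; band mean = gray %*% A / counts
    A <- matrix(0, sum(inside), n_bands)
    A[cbind(which(use), idx[use])] <- 1
    counts <- colSums(A)
    nz <- counts > 0
    vals <- gray %*% A
    out[, nz] <- sweep(vals[, nz, drop = FALSE], 2, counts[nz], "/")
  }
  attr(out, "wavelength_nm") <- (band_edges[-1] + band_edges[-(n_bands + 1)]) / 2
  out
}

#' Assemble a hypercube from a push-broom frame sequence
#'
#' Stitches the per-frame (slit row x band) lines in frame order into the
#' full scan-line x slit-row x band cube.
#'
#' @param frames list of `rows x cols x 3` arrays, or a `frame_sequence`
#'   from [read_frames()], or a `scan_result` from [render_scan()].
#' @param calib a `dispersion_model`.
#' @param band_edges ascending band-edge vector (default: the calibration's
#'   native per-column grid).
#' @return a `hypercube` with `scan_lines = length(frames)`.
#' @export
assemble_cube <- function(frames, calib, band_edges = native_band_edges(calib)) {
  if (inherits(frames, "scan_result")) frames <- frames$frames
  if (inherits(frames, "frame_sequence")) frames <- frames$frames
  if (!length(frames)) stop("assemble_cube: no frames")
  d1 <- dim(frames[[1]])
  for (f in seq_along(frames)) {
    if (!identical(dim(frames[[f]]), d1))
      stop("assemble_cube: frame ", f, " has dimensions ",
           paste(dim(frames[[f]]), collapse = "x"), ", expected ",
           paste(d1, collapse = "x"))
  }
  lines <- lapply(frames, frame_to_line, calib = calib, band_edges = band_edges)
  centers <- attr(lines[[1]], "wavelength_nm")
  data <- array(NA_real_, dim = c(length(frames), d1[1], length(centers)))
  for (f in seq_along(lines)) data[f, , ] <- lines[[f]]
  hypercube(data, centers,
            provenance = list(source = "assemble_cube",
                              n_frames = length(frames)))
}

#' Band-integrated spatial image
#'
#' Per-pixel sum of the band values whose band centre lies in the half-open
#' window `[lo_nm, hi_nm)`. Invalid bands are excluded. Integrating the full
#' axis yields the panchromatic spatial image of a scan.
#'
#' @param cube a `hypercube`.
#' @param lo_nm,hi_nm integration window, `lo < hi`, overlapping the axis.
#' @return matrix `scan_lines x slit_rows`.
#' @export
band_integrate <- function(cube, lo_nm, hi_nm) {
  stopifnot(inherits(cube, "hypercube"))
  if (lo_nm >= hi_nm) stop("band_integrate: need lo_nm < hi_nm")
  sel <- cube$wavelength_nm >= lo_nm & cube$wavelength_nm < hi_nm & cube$valid
  if (!any(sel))
    stop("band_integrate: no valid band centre in [", lo_nm, ", ", hi_nm, ")")
  apply(cube$data[, , sel, drop = FALSE], c(1, 2), sum)
}

#' Mean spectrum of a rectangular region
#'
#' @param cube a `hypercube`.
#' @param region integer vector `c(scan0, scan1, row0, row1)` (inclusive,
#'   1-based) selecting a non-empty in-bounds rectangle.
#' @return data.frame `(wavelength_nm, intensity)`, invalid bands `NA`;
#'   attribute `n_pixels` records the region size.
#' @export
extract_spectrum <- function(cube, region) {
  stopifnot(inherits(cube, "hypercube"))
  region <- as.integer(region)
  if (length(region) != 4L) stop("extract_spectrum: region must be c(scan0, scan1, row0, row1)")
  d <- dim(cube$data)
  if (region[1] > region[2] || region[3] > region[4])
    stop("extract_spectrum: empty region")
  if (region[1] < 1L || region[2] > d[1] || region[3] < 1L || region[4] > d[2])
    stop("extract_spectrum: region out of bounds (cube is ", d[1], " x ", d[2], ")")
  sub <- cube$data[region[1]:region[2], region[3]:region[4], , drop = FALSE]
  spec <- apply(sub, 3, mean)
  out <- data.frame(wavelength_nm = cube$wavelength_nm, intensity = spec)
  attr(out, "n_pixels") <- (region[2] - region[1] + 1L) * (region[4] - region[3] + 1L)
  out
}

#' Feature width (FWHM) of a line profile
#'
#' Width at half depth/height of the profile's dominant feature. The
#' baseline is the profile median; the feature is the global extremum
#' farther from the baseline (a trough for a dark feature such as a
#' spectacle frame crossing skin, a peak for a bright one). The half level
#' is midway between baseline and extremum; the two crossings adjacent to
#' the extremum are located by linear interpolation, and the width is their
#' distance, optionally scaled to millimetres.
#'
#' @param positions ascending positions (pixels unless `scale` converts).
#' @param intensity profile values, same length.
#' @param scale multiplicative position-to-output unit factor (e.g. mm per
#'   pixel at the working distance); default 1.
#' @return list: `fwhm` (in output units), `crossings` (the two interpolated
#'   half-level positions, input units), `half_level`, `baseline`,
#'   `feature` (`"trough"` or `"peak"`).
#' @export
profile_fwhm <- function(positions, intensity, scale = 1) {
  positions <- as.numeric(positions); y <- as.numeric(intensity)
  if (length(positions) != length(y) || length(y) < 3L)
    stop("profile_fwhm: positions and intensity must match, length >= 3")
  if (any(diff(positions) <= 0)) stop("profile_fwhm: positions must be ascending")
  base <- stats::median(y)
  i_min <- which.min(y); i_max <- which.max(y)
  trough <- (base - y[i_min]) >= (y[i_max] - base)
  i0 <- if (trough) i_min else i_max
  extremum <- y[i0]
  if (extremum == base)
    stop("profile_fwhm: profile has no feature (extremum equals baseline)")
  half <- base - (base - extremum) / 2
  # signed deviation below (trough) / above (peak) the half level
  dev <- if (trough) half - y else y - half
  if (dev[i0] <= 0) stop("profile_fwhm: degenerate feature")
  cross_at <- function(i, j) {
    # dev changes sign between i and j
    positions[i] + (0 - dev[i]) / (dev[j] - dev[i]) * (positions[j] - positions[i])
  }
  li <- i0
  while (li > 1L && dev[li - 1L] > 0) li <- li - 1L
  if (li == 1L) stop("profile_fwhm: feature clipped at the left edge")
  ri <- i0
  n <- length(y)
  while (ri < n && dev[ri + 1L] > 0) ri <- ri + 1L
  if (ri == n) stop("profile_fwhm: feature clipped at the right edge")
  x1 <- cross_at(li - 1L, li)
  x2 <- cross_at(ri + 1L, ri)
  list(fwhm = (x2 - x1) * scale, crossings = c(x1, x2),
       half_level = half, baseline = base,
       feature = if (trough) "trough" else "peak")
}
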