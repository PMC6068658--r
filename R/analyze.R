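#' Reflected light ratio index (RLRI) image
#'
#' RLRI = (NIR - RED) / (NIR + RED), with NIR the band-integrated intensity
#' over 740-750 nm and RED over 680-690 nm. Vegetation absorbs 680-690 nm
#' light (chlorophyll) and reflects strongly at 740-750 nm (the red edge),
#' so vegetation pixels score high. This in-range index substitutes for
#' NDVI on instruments whose sensitivity ends at 750 nm (NDVI's 800 nm NIR
#' band is out of reach and deliberately not implemented).
#'
#' Both integrals are half-open band sums; because the ratio normalises the
#' two windows, sums and means differ only when the windows contain unequal
#' band counts. The index is computed on raw DN spectra; pass a
#' response-corrected cube to compute it on corrected data.
#'
#' @param cube a `hypercube`.
#' @param nir_window,red_window length-2 nm windows, each overlapping the
#'   wavelength axis.
#' @return an object of class `index_image`: `values`
#'   (`scan_lines x slit_rows`, in `[-1, 1]`, `NA` where invalid), `valid`
#'   logical matrix (pixels with NIR + RED = 0 masked), and the windows.
#' @export
rlri <- function(cube, nir_window = c(740, 750), red_window = c(680, 690)) {
  stopifnot(inherits(cube, "hypercube"))
  nir <- band_integrate(cube, nir_window[1], nir_window[2])
  red <- band_integrate(cube, red_window[1], red_window[2])
  tot <- nir + red
  valid <- is.finite(tot) & tot > 0
  values <- matrix(NA_real_, nrow(tot), ncol(tot))
  values[valid] <- (nir[valid] - red[valid]) / tot[valid]
  structure(list(values = values, valid = valid,
                 nir_window = nir_window, red_window = red_window),
            class = "index_image")
}

#' @export
print.index_image <- function(x, ...) {
  cat("Index image ", nrow(x$values), " x ", ncol(x$values),
      ": NIR ", x$nir_window[1], "-", x$nir_window[2],
      " nm, RED ", x$red_window[1], "-", x$red_window[2], " nm; ",
      sum(x$valid), " valid pixels\n", sep = "")
  invisible(x)
}

#' Threshold an index image into a binary map
#'
#' A pixel is set (vegetation) when its index value is strictly greater
#' than the threshold; a value exactly at the threshold is not set. Invalid
#' pixels are excluded from both the set count and the denominator, so the
#' coverage fraction is (set pixels) / (valid pixels).
#'
#' @param index an `index_image`.
#' @param threshold decision threshold in (-1, 1); default 0.3.
#' @return an object of class `binary_mask`: `mask` logical matrix (`NA`
#'   where invalid), `threshold`, `coverage`, `n_valid`.
#' @export
threshold_mask <- function(index, threshold = 0.3) {
  stopifnot(inherits(index, "index_image"))
  if (threshold <= -1 || threshold >= 1)
    stop("threshold_mask: threshold must be in (-1, 1)")
  mask <- matrix(NA, nrow(index$values), ncol(index$values))
  mask[index$valid] <- index$values[index$valid] > threshold
  n_valid <- sum(index$valid)
  coverage <- if (n_valid) sum(mask[index$valid]) / n_valid else NA_real_
  structure(list(mask = mask, threshold = threshold,
                 coverage = coverage, n_valid = n_valid),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("Binary mask ", nrow(x$mask), " x ", ncol(x$mask),
      ", threshold ", x$threshold, ": coverage ",
      format(100 * x$coverage, digits = 4), "% of ", x$n_valid,
      " valid pixels\n", sep = "")
  invisible(x)
}

#' Overlay a binary mask on a grayscale image
#'
#' Tints set pixels red and unset pixels blue, alpha-blended over the base
#' image (the spatial image of the scan). Invalid pixels are left untinted.
#'
#' @param base numeric matrix, same dimensions as the mask; rescaled to
#'   `[0, 1]` for display.
#' @param mask a `binary_mask`.
#' @param alpha blend factor in `[0, 1]`; 0 returns the base unchanged.
#' @return numeric array `rows x cols x 3` (RGB in `[0, 1]`).
#' @export
overlay <- function(base, mask, alpha = 0.5) {
  stopifnot(inherits(mask, "binary_mask"), is.matrix(base))
  if (!identical(dim(base), dim(mask$mask)))
    stop("overlay: base is ", paste(dim(base), collapse = "x"),
         " but mask is ", paste(dim(mask$mask), collapse = "x"))
  if (alpha < 0 || alpha > 1) stop("overlay: alpha must be in [0, 1]")
  rng <- range(base, finite = TRUE)
  g <- if (diff(rng) > 0) (base - rng[1]) / diff(rng) else base * 0
  out <- array(rep(g, 3), dim = c(dim(base), 3))
  set <- which(mask$mask)          # NA-safe: which() drops NA
  unset <- which(!mask$mask)
  for (ch in 1:3) {
    tint_set <- if (ch == 1) 1 else 0    # red
    tint_unset <- if (ch == 3) 1 else 0  # blue
    plane <- out[, , ch]
    plane[set] <- (1 - alpha) * g[set] + alpha * tint_set
    plane[unset] <- (1 - alpha) * g[unset] + alpha * tint_unset
    out[, , ch] <- plane
  }
  out
}

#' Normalize a spectrum at an anchor wavelength
#'
#' Divides the whole spectrum by its (linearly interpolated) value at the
#' anchor, conventionally 550 nm, so spectra of differently lit objects can
#' be compared shape-to-shape.
#'
#' @param spectrum data.frame `(wavelength_nm, intensity)`.
#' @param anchor_nm anchor wavelength, inside the spectrum's range.
#' @return data.frame with intensity scaled so the anchor value is 1.
#' @export
normalize_at <- function(spectrum, anchor_nm = 550) {
  sp <- .as_spectrum_df(spectrum, "spectrum")
  if (anchor_nm < min(sp$wavelength_nm) || anchor_nm > max(sp$wavelength_nm))
    stop("normalize_at: anchor ", anchor_nm, " nm outside the spectrum range")
  v <- stats::approx(sp$wavelength_nm, sp$intensity, xout = anchor_nm)$y
  if (!is.finite(v) || v <= 0)
    stop("normalize_at: intensity at the anchor is not positive")
  sp$intensity <- sp$intensity / v
  sp
}

#' Detect absorption troughs in a spectrum
#'
#' Finds local reflectance minima (absorption features such as the
#' oxyhemoglobin bands at 419 and 573 nm or the chlorophyll trough near
#' 650 nm): the spectrum is smoothed with a moving average of the stated
#' wavelength window, negated, and peaks with prominence at least
#' `min_depth_fraction` of the smoothed dynamic range are detected and
#' refined to nm by parabolic interpolation. The local continuum is the
#' smoothed spectrum itself, so the reported depth is the topographic
#' prominence of the trough.
#'
#' @param spectrum data.frame `(wavelength_nm, intensity)`, length >= 5.
#' @param smooth_window_nm moving-average window, nm.
#' @param min_depth_fraction required depth as a fraction of the smoothed
#'   spectrum's dynamic range.
#' @return a `trough_set`: data.frame `(wavelength_nm, depth)`, possibly
#'   empty; sorted by wavelength.
#' @export
find_troughs <- function(spectrum, smooth_window_nm = 10,
                         min_depth_fraction = 0.05) {
  sp <- .as_spectrum_df(spectrum, "spectrum")
  ok <- is.finite(sp$intensity)
  sp <- sp[ok, ]
  if (nrow(sp) < 5L) stop("find_troughs: need at least 5 finite samples")
  spacing <- stats::median(diff(sp$wavelength_nm))
  w <- max(1L, round(smooth_window_nm / spacing))
  y <- .moving_average(sp$intensity, w)
  empty <- structure(data.frame(wavelength_nm = numeric(0), depth = numeric(0)),
                     class = c("trough_set", "data.frame"))
  if (max(y) == min(y)) return(empty)
  pk <- detect_peaks(-y, min_prominence_fraction = min_depth_fraction)
  if (!nrow(pk)) return(empty)
  wl <- stats::approx(seq_along(y), sp$wavelength_nm, xout = pk$position)$y
  structure(data.frame(wavelength_nm = wl, depth = pk$prominence),
            class = c("trough_set", "data.frame"))
}

# centered moving average with shrinking window at the edges
.moving_average <- function(y, w) {
  if (w <= 1L) return(y)
  half <- (w - 1L) %/% 2L
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
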