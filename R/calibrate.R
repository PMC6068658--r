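#' Detect peaks in a 1-D spectrum
#'
#' Local maxima whose topographic prominence is at least
#' `min_prominence_fraction` of the spectrum's dynamic range, with sub-sample
#' position refinement by parabolic interpolation through the maximum and its
#' two neighbours. Pixel-scale line positions are refined this way because
#' wavelength errors on the 0.1 nm scale imply sub-pixel accuracy at
#' typical ~0.4 nm/column sampling.
#'
#' @param spectrum numeric intensity per position (length >= 3).
#' @param min_prominence_fraction required prominence as a fraction of
#'   `max(spectrum) - min(spectrum)`, in (0, 1).
#' @param min_separation minimum distance between reported peaks, in
#'   samples; when two qualifying peaks are closer, the taller one wins.
#'   Quantization staircases can split one physical line into twin maxima
#'   one or two samples apart, and no real feature can be narrower than the
#'   instrument linewidth, so a separation floor on that scale is safe.
#'   Default 1 (no suppression).
#' @return a `peak_set`: data.frame with columns `position` (fractional
#'   index), `height`, `prominence`, sorted by position. A flat spectrum
#'   yields an empty set.
#' @export
detect_peaks <- function(spectrum, min_prominence_fraction = 0.05,
                         min_separation = 1) {
  y <- as.numeric(spectrum)
  if (length(y) < 3L) stop("detect_peaks: spectrum length must be >= 3")
  if (any(!is.finite(y))) stop("detect_peaks: spectrum must be finite")
  if (min_prominence_fraction <= 0 || min_prominence_fraction >= 1)
    stop("detect_peaks: min_prominence_fraction must be in (0, 1)")
  rng <- max(y) - min(y)
  empty <- structure(
    data.frame(position = numeric(0), height = numeric(0),
               prominence = numeric(0)),
    class = c("peak_set", "data.frame"))
  if (rng == 0) return(empty)

  n <- length(y)
  # strict local maxima; leading edge of any plateau
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  cand <- cand[y[cand] > y[cand - 1L]]
  if (!length(cand)) return(empty)

  prom <- vapply(cand, function(i) .prominence(y, i), numeric(1))
  keep <- prom >= min_prominence_fraction * rng
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)

  if (min_separation > 1 && length(cand) > 1L) {
    ord <- order(y[cand], prom, decreasing = TRUE)
    taken <- logical(length(cand))
    for (k in ord) {
      if (any(taken & abs(cand - cand[k]) < min_separation)) next
      taken[k] <- TRUE
    }
    cand <- cand[taken]; prom <- prom[taken]
  }

  pos <- numeric(length(cand)); hgt <- numeric(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    if (i > 1L && i < n) {
      denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
      dx <- if (denom < 0) 0.5 * (y[i - 1L] - y[i + 1L]) / denom else 0
      dx <- max(-0.5, min(0.5, dx))
      pos[k] <- i + dx
      hgt[k] <- y[i] - 0.25 * (y[i - 1L] - y[i + 1L]) * dx
    } else {
      pos[k] <- i; hgt[k] <- y[i]
    }
  }
  ord <- order(pos)
  structure(data.frame(position = pos[ord], height = hgt[ord],
                       prominence = prom[ord]),
            class = c("peak_set", "data.frame"))
}

# topographic prominence of the local maximum at index i: height above the
# higher of the two key saddles reached before meeting strictly taller
# terrain (ends of the signal count as bases)
.prominence <- function(y, i) {
  n <- length(y)
  lmin <- y[i]
  j <- i
  while (j > 1L) {
    j <- j - 1L
    if (y[j] > y[i]) break
    if (y[j] < lmin) lmin <- y[j]
  }
  left <- if (y[j] > y[i]) lmin else min(y[1:i])
  rmin <- y[i]
  j <- i
  while (j < n) {
    j <- j + 1L
    if (y[j] > y[i]) break
    if (y[j] < rmin) rmin <- y[j]
  }
  right <- if (y[j] > y[i]) rmin else min(y[i:n])
  y[i] - max(left, right)
}

#' Pair detected peaks with reference emission lines
#'
#' Order-preserving pairing of detected peak columns with reference line
#' wavelengths. With equal counts, pairing is by rank. With unequal counts,
#' the order-preserving subset of the longer list that minimises the summed
#' squared residuals of a provisional linear wavelength fit is selected by
#' exhaustive search.
#'
#' @param detected a `peak_set` (positions in pixel columns) or numeric
#'   vector of columns.
#' @param reference an `emission_lines` object or numeric vector of nm.
#' @return data.frame with columns `column`, `wavelength_nm` (>= 2 rows).
#' @export
match_peaks <- function(detected, reference) {
  cols <- if (inherits(detected, "peak_set")) detected$position else as.numeric(detected)
  refs <- if (inherits(reference, "emission_lines")) reference$wavelength_nm else as.numeric(reference)
  if (length(cols) < 2L || length(refs) < 2L)
    stop("match_peaks: need at least 2 detected peaks and 2 reference lines")
  if (any(diff(cols) <= 0) || any(diff(refs) <= 0))
    stop("match_peaks: inputs must be strictly increasing")

  nd <- length(cols); nr <- length(refs)
  if (nd == nr)
    return(data.frame(column = cols, wavelength_nm = refs))

  m <- min(nd, nr)
  long <- if (nd > nr) cols else refs
  n_long <- length(long)
  if (choose(n_long, m) > 1e5)
    stop("match_peaks: too many candidate pairings (", n_long, " choose ", m,
         "); clean up the peak list first")
  subsets <- utils::combn(n_long, m)
  best <- NULL; best_ss <- Inf
  for (s in seq_len(ncol(subsets))) {
    idx <- subsets[, s]
    cc <- if (nd > nr) long[idx] else cols
    ww <- if (nd > nr) refs else long[idx]
    fit <- stats::lm.fit(cbind(1, cc), ww)
    ss <- sum(fit$residuals^2)
    if (ss < best_ss) {
      best_ss <- ss
      best <- data.frame(column = cc, wavelength_nm = ww)
    }
  }
  best
}

#' Fit a dispersion model to (column, wavelength) pairs
#'
#' Least-squares polynomial fit of wavelength on pixel column. The fitted
#' model must be strictly monotone over the data's column span; a
#' non-monotone fit is rejected with advice to reduce the order.
#'
#' @param pairs data.frame with columns `column` and `wavelength_nm`
#'   (as returned by [match_peaks()]).
#' @param order polynomial order, 1 (default) or 2.
#' @param col_range columns over which the model is declared valid
#'   (default: the span of the calibration pairs). Widen to the full sensor,
#'   e.g. `c(1, sensor_cols)`, to use bands beyond the outermost lamp line;
#'   monotonicity is then verified over the widened range.
#' @return a `dispersion_model` with per-pair residuals recorded.
#' @export
fit_dispersion <- function(pairs, order = 1, col_range = NULL) {
  stopifnot(is.data.frame(pairs), all(c("column", "wavelength_nm") %in% names(pairs)))
  if (!order %in% c(1, 2)) stop("fit_dispersion: order must be 1 or 2")
  n <- nrow(pairs)
  if (n < order + 1)
    stop("fit_dispersion: underdetermined - need at least ", order + 1,
         " pairs for order ", order)
  X <- stats::poly(pairs$column, degree = order, raw = TRUE)
  fit <- stats::lm(pairs$wavelength_nm ~ X)
  coef <- unname(stats::coef(fit))
  if (is.null(col_range)) col_range <- range(pairs$column)
  model <- tryCatch(
    dispersion_model(coef, col_range,
                     residuals_nm = unname(stats::residuals(fit))),
    error = function(e)
      stop("fit_dispersion: fitted polynomial is not monotone over the data ",
           "span; reduce the fit order", call. = FALSE))
  model
}

#' Wavelength calibration error statistics
#'
#' Elementwise absolute differences between a measured and a reference line
#' list, summarised by minimum, median and maximum. The median of an even
#' count is the mean of the two central values. Both lists must be sorted
#' ascending (the pairing is positional).
#'
#' @param measured_nm measured line wavelengths, ascending.
#' @param reference_nm reference line wavelengths, ascending, same length.
#' @return an object of class `calibration_error_stats` with fields
#'   `errors_nm`, `min_nm`, `median_nm`, `max_nm`.
#' @export
calibration_error_stats <- function(measured_nm, reference_nm) {
  measured_nm <- as.numeric(measured_nm)
  reference_nm <- as.numeric(reference_nm)
  if (length(measured_nm) != length(reference_nm))
    stop("calibration_error_stats: length mismatch")
  if (length(measured_nm) < 1L)
    stop("calibration_error_stats: need at least one line")
  if (is.unsorted(measured_nm, strictly = FALSE) ||
      is.unsorted(reference_nm, strictly = FALSE))
    stop("calibration_error_stats: inputs must be sorted ascending")
  err <- abs(measured_nm - reference_nm)
  structure(list(errors_nm = err,
                 min_nm = min(err),
                 median_nm = stats::median(err),
                 max_nm = max(err)),
            class = "calibration_error_stats")
}

#' @export
print.calibration_error_stats <- function(x, ...) {
  cat("Wavelength calibration errors over", length(x$errors_nm), "lines:\n")
  cat("  min", format(x$min_nm, digits = 3), "nm,",
      "median", format(x$median_nm, digits = 3), "nm,",
      "max", format(x$max_nm, digits = 3), "nm\n")
  invisible(x)
}

#' Compute the radiometric response correction curve
#'
#' The instrument's relative intensity response is removed by the ratio
#' I_std(lambda) / I_det(lambda), where I_std is the spectrum of a common
#' source measured by a trusted spectrometer and I_det the same source seen
#' by the instrument. Both are linearly interpolated onto the detected
#' spectrum's grid restricted to the overlap. The factor is only defined
#' where the detected signal is at least `floor_fraction` of its maximum
#' (the ratio diverges where the detector signal vanishes) and inside the
#' valid window, 400-650 nm by default.
#'
#' @param standard data.frame `(wavelength_nm, intensity)` from the
#'   reference spectrometer.
#' @param detected data.frame `(wavelength_nm, intensity)` from this
#'   instrument, same source.
#' @param floor_fraction detected-signal floor as a fraction of its max.
#' @param valid_window length-2 nm window where the curve is trusted.
#' @return an object of class `response_curve` with fields `wavelength_nm`,
#'   `factor`, `valid`.
#' @export
compute_response <- function(standard, detected, floor_fraction = 0.05,
                             valid_window = c(400, 650)) {
  std <- .as_spectrum_df(standard, "standard")
  det <- .as_spectrum_df(detected, "detected")
  if (floor_fraction <= 0 || floor_fraction >= 1)
    stop("compute_response: floor_fraction must be in (0, 1)")
  lo <- max(min(std$wavelength_nm), min(det$wavelength_nm))
  hi <- min(max(std$wavelength_nm), max(det$wavelength_nm))
  if (lo >= hi)
    stop("compute_response: wavelength ranges do not overlap")
  keep <- det$wavelength_nm >= lo & det$wavelength_nm <= hi
  wl <- det$wavelength_nm[keep]
  idet <- det$intensity[keep]
  istd <- stats::approx(std$wavelength_nm, std$intensity, xout = wl)$y
  valid <- idet >= floor_fraction * max(idet) &
    wl >= valid_window[1] & wl <= valid_window[2]
  factor <- rep(NA_real_, length(wl))
  factor[valid] <- istd[valid] / idet[valid]
  valid[valid] <- is.finite(factor[valid]) & factor[valid] > 0
  factor[!valid] <- NA_real_
  structure(list(wavelength_nm = wl, factor = factor, valid = valid),
            class = "response_curve")
}

.as_spectrum_df <- function(x, what) {
  if (is.data.frame(x)) {
    nm <- names(x)
    wcol <- intersect(c("wavelength_nm", "wavelength"), nm)[1]
    icol <- intersect(c("intensity", "reflectance"), nm)[1]
    if (is.na(wcol) || is.na(icol))
      stop("expected ", what, " as a data.frame with wavelength and intensity columns")
    out <- data.frame(wavelength_nm = as.numeric(x[[wcol]]),
                      intensity = as.numeric(x[[icol]]))
  } else if (inherits(x, "reflectance_spectrum")) {
    out <- data.frame(wavelength_nm = x$wavelength_nm, intensity = x$reflectance)
  } else stop("cannot interpret ", what, " as a spectrum")
  if (any(diff(out$wavelength_nm) <= 0))
    stop(what, ": wavelength grid must be strictly ascending")
  out
}

#' Apply a response curve to a spectrum
#'
#' Multiplies the spectrum by the correction factor where the curve is
#' valid. Outside the valid mask the output is `NA` (flagged invalid rather
#' than silently passed through).
#'
#' @param spectrum data.frame `(wavelength_nm, intensity)`; its grid must
#'   lie within the curve's grid.
#' @param curve a `response_curve`.
#' @return data.frame `(wavelength_nm, intensity, valid)`.
#' @export
apply_response <- function(spectrum, curve) {
  stopifnot(inherits(curve, "response_curve"))
  sp <- .as_spectrum_df(spectrum, "spectrum")
  if (min(sp$wavelength_nm) < min(curve$wavelength_nm) - 1e-9 ||
      max(sp$wavelength_nm) > max(curve$wavelength_nm) + 1e-9)
    stop("apply_response: spectrum grid extends beyond the response curve")
  f <- stats::approx(curve$wavelength_nm, curve$factor,
                     xout = sp$wavelength_nm)$y
  # a point is valid only when both bracketing curve samples are valid
  v <- stats::approx(curve$wavelength_nm, as.numeric(curve$valid),
                     xout = sp$wavelength_nm)$y >= 1 - 1e-12
  v[is.na(v) | is.na(f)] <- FALSE
  out <- sp
  out$intensity <- ifelse(v, sp$intensity * f, NA_real_)
  out$valid <- v
  out
}

#' Serialize a response curve to JSON
#' @param curve a `response_curve`.
#' @param path output file path.
#' @export
write_response_json <- function(curve, path) {
  stopifnot(inherits(curve, "response_curve"))
  jsonlite::write_json(
    list(type = "response_curve", wavelength_nm = curve$wavelength_nm,
         factor = curve$factor, valid = curve$valid),
    path, digits = NA, auto_unbox = FALSE, null = "null", na = "null")
  invisible(path)
}

#' Read a response curve from JSON
#' @param path JSON file written by [write_response_json()].
#' @return a `response_curve`.
#' @export
read_response_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$type) || x$type != "response_curve")
    stop("read_response_json: ", path, " is not a response curve file")
  structure(list(wavelength_nm = as.numeric(x$wavelength_nm),
                 factor = as.numeric(x$factor),
                 valid = as.logical(x$valid)),
            class = "response_curve")
}
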