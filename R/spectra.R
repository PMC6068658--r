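#' Emission-line source
#'
#' A line lamp described by a table of emission lines. When rendered onto a
#' wavelength grid each line becomes a Gaussian of standard deviation
#' `linewidth_nm`, peaking at the line's relative intensity. The default
#' sigma of 5.5 nm (FWHM about 13 nm) matches the roughly 15 nm spectral
#' resolution of a compact grating-prism spectrometer while keeping the
#' closely spaced yellow/orange lamp lines individually resolvable, as they
#' are on the real instrument.
#'
#' @param wavelength_nm strictly increasing line centres in nm.
#' @param intensity relative line intensities, finite and non-negative.
#' @param linewidth_nm Gaussian sigma with which each line is rendered, nm.
#' @return an object of class `emission_lines`.
#' @export
emission_lines <- function(wavelength_nm, intensity = rep(1, length(wavelength_nm)),
                           linewidth_nm = 5.5) {
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  if (length(wavelength_nm) < 1L)
    stop("emission_lines: at least one line is required")
  if (length(intensity) != length(wavelength_nm))
    stop("emission_lines: wavelength and intensity lengths differ")
  if (any(!is.finite(wavelength_nm)) || any(diff(wavelength_nm) <= 0))
    stop("emission_lines: wavelengths must be finite and strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("emission_lines: intensities must be finite and non-negative")
  if (!is.finite(linewidth_nm) || linewidth_nm <= 0)
    stop("emission_lines: linewidth_nm must be positive")
  structure(list(wavelength_nm = wavelength_nm, intensity = intensity,
                 linewidth_nm = linewidth_nm),
            class = "emission_lines")
}

#' Reference mercury lamp line table
#'
#' The seven visible Hg lamp lines used for wavelength calibration:
#' 405.7, 437, 547.4, 578.9, 595.3, 621.1 and 699.2 nm. Relative
#' intensities are nominal (line tables give only the wavelengths).
#'
#' @param linewidth_nm rendered Gaussian sigma, nm.
#' @param power peak spectral power of the strongest line (DN-scale units);
#'   leave at 1 when using the table as a calibration reference, raise it
#'   (e.g. 160) when using the lamp as a simulated illuminant.
#' @return an `emission_lines` object.
#' @export
mercury_lines <- function(linewidth_nm = 5.5, power = 1) {
  emission_lines(
    wavelength_nm = c(405.7, 437, 547.4, 578.9, 595.3, 621.1, 699.2),
    intensity     = power * c(0.55, 0.80, 1.00, 0.75, 0.50, 0.85, 0.30),
    linewidth_nm  = linewidth_nm
  )
}

#' Reflectance spectrum
#'
#' @param wavelength_nm ascending wavelength grid, nm.
#' @param reflectance reflectance in `[0, 1]`, same length as the grid
#'   (values are clipped into the unit interval).
#' @param label material name.
#' @return an object of class `reflectance_spectrum`.
#' @export
reflectance_spectrum <- function(wavelength_nm, reflectance, label = "material") {
  wavelength_nm <- as.numeric(wavelength_nm)
  reflectance <- as.numeric(reflectance)
  if (length(wavelength_nm) != length(reflectance))
    stop("reflectance_spectrum: grid and reflectance lengths differ")
  if (length(wavelength_nm) < 2L || any(diff(wavelength_nm) <= 0))
    stop("reflectance_spectrum: wavelength grid must be ascending, length >= 2")
  if (any(!is.finite(reflectance)))
    stop("reflectance_spectrum: reflectance must be finite")
  reflectance <- pmin(pmax(reflectance, 0), 1)
  structure(list(wavelength_nm = wavelength_nm, reflectance = reflectance,
                 label = label),
            class = "reflectance_spectrum")
}

#' Evaluate a spectral quantity on a wavelength grid
#'
#' Common evaluation interface for illuminants and materials. Reflectance
#' spectra interpolate linearly and return 0 outside their grid; emission
#' line sources evaluate their Gaussian line sum; plain functions are called
#' with the grid; a single number is treated as a flat spectrum.
#'
#' @param x spectral object, function of wavelength, or scalar.
#' @param wavelength_nm numeric grid to evaluate on.
#' @return numeric vector, one value per grid point.
#' @export
eval_spectrum <- function(x, wavelength_nm) {
  UseMethod("eval_spectrum")
}

#' @export
eval_spectrum.reflectance_spectrum <- function(x, wavelength_nm) {
  stats::approx(x$wavelength_nm, x$reflectance, xout = wavelength_nm,
                yleft = 0, yright = 0)$y
}

#' @export
eval_spectrum.emission_lines <- function(x, wavelength_nm) {
  out <- numeric(length(wavelength_nm))
  s2 <- 2 * x$linewidth_nm^2
  for (i in seq_along(x$wavelength_nm)) {
    out <- out + x$intensity[i] * exp(-(wavelength_nm - x$wavelength_nm[i])^2 / s2)
  }
  out
}

#' @export
eval_spectrum.function <- function(x, wavelength_nm) {
  v <- x(wavelength_nm)
  if (length(v) == 1L) v <- rep(v, length(wavelength_nm))
  as.numeric(v)
}

#' @export
eval_spectrum.numeric <- function(x, wavelength_nm) {
  if (length(x) != 1L)
    stop("eval_spectrum: numeric spectra must be scalar (flat)")
  rep(as.numeric(x), length(wavelength_nm))
}

#' Flat illuminant
#'
#' @param power spectral power (DN-scale units) at every wavelength.
#' @return a function of wavelength usable wherever an illuminant is expected.
#' @export
flat_illuminant <- function(power = 160) {
  force(power)
  function(wavelength_nm) rep(power, length(wavelength_nm))
}

#' White-LED illuminant
#'
#' Blue pump plus broad phosphor emission, the usual white-LED shape used
#' for response calibration and underwater illumination.
#'
#' @param power peak spectral power (DN-scale units).
#' @return a function of wavelength.
#' @export
led_illuminant <- function(power = 160) {
  force(power)
  function(wavelength_nm) {
    power * (0.9 * exp(-(wavelength_nm - 450)^2 / (2 * 12^2)) +
             0.75 * exp(-(wavelength_nm - 560)^2 / (2 * 60^2)))
  }
}

# smooth logistic step used by several builtin spectra
.sigmoid <- function(x) 1 / (1 + exp(-x))

# multiplicative Gaussian absorption trough
.trough <- function(wl, center, depth, sigma) {
  1 - depth * exp(-(wl - center)^2 / (2 * sigma^2))
}

#' Builtin library of reflectance spectra
#'
#' Idealised material spectra on a 400-760 nm grid, used by the forward
#' simulator as ground truth: vegetation with a chlorophyll red edge
#' (low reflectance 680-690 nm, high 740-750 nm), a neutral building
#' surface, lip and cheek skin with oxyhemoglobin troughs at 419 nm
#' (Soret) and 573 nm (shallower on the cheek, which is less blood-rich),
#' and green vs ripe banana skin (chlorophyll trough near 650 nm present
#' only while green).
#'
#' @param step_nm grid spacing in nm.
#' @return named list of `reflectance_spectrum` objects.
#' @export
builtin_spectral_library <- function(step_nm = 1) {
  wl <- seq(400, 760, by = step_nm)

  veg <- 0.05 + 0.02 * exp(-(wl - 550)^2 / (2 * 30^2)) +
    0.55 * .sigmoid((wl - 712) / 10)
  skin_base <- function(depth419, depth573) {
    base <- 0.12 + 0.45 * .sigmoid((wl - 590) / 55)
    base * .trough(wl, 419, depth419, 9) * .trough(wl, 573, depth573, 11)
  }
  green_banana <- (0.08 + 0.45 * .sigmoid((wl - 520) / 35)) *
    .trough(wl, 650, 0.45, 14)
  ripe_banana <- 0.10 + 0.62 * .sigmoid((wl - 510) / 28)

  list(
    vegetation   = reflectance_spectrum(wl, veg, "vegetation"),
    building     = reflectance_spectrum(wl, rep(0.35, length(wl)), "building"),
    lips         = reflectance_spectrum(wl, skin_base(0.55, 0.40), "lips"),
    cheek        = reflectance_spectrum(wl, skin_base(0.45, 0.18), "cheek"),
    green_banana = reflectance_spectrum(wl, green_banana, "green_banana"),
    ripe_banana  = reflectance_spectrum(wl, ripe_banana, "ripe_banana"),
    white        = reflectance_spectrum(wl, rep(1, length(wl)), "white")
  )
}

#' @export
print.emission_lines <- function(x, ...) {
  cat("Emission-line source:", length(x$wavelength_nm), "lines,",
      "sigma", format(x$linewidth_nm, digits = 4), "nm\n")
  print(data.frame(wavelength_nm = x$wavelength_nm, intensity = x$intensity))
  invisible(x)
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  cat("Reflectance spectrum '", x$label, "': ",
      length(x$wavelength_nm), " points, ",
      min(x$wavelength_nm), "-", max(x$wavelength_nm), " nm\n", sep = "")
  invisible(x)
}
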