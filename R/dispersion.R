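#' Pixel-column to wavelength dispersion model
#'
#' A polynomial mapping lambda(col) = c0 + c1*col + c2*col^2 + ... from
#' detector pixel column to wavelength in nm, valid and strictly monotone
#' over a stated column range. This is both the calibration product and the
#' simulator's ground truth.
#'
#' @param coefficients polynomial coefficients, lowest order first.
#' @param col_range length-2 numeric, valid column range (inclusive).
#' @param residuals_nm optional per-line fit residuals in nm.
#' @return an object of class `dispersion_model`.
#' @export
dispersion_model <- function(coefficients, col_range, residuals_nm = NULL) {
  coefficients <- as.numeric(coefficients)
  col_range <- as.numeric(col_range)
  if (length(coefficients) < 2L)
    stop("dispersion_model: need at least intercept and slope")
  if (length(col_range) != 2L || col_range[1] >= col_range[2])
    stop("dispersion_model: col_range must be an increasing pair")
  m <- structure(list(coefficients = coefficients, col_range = col_range,
                      residuals_nm = residuals_nm),
                 class = "dispersion_model")
  cols <- seq(col_range[1], col_range[2], length.out = 257L)
  wl <- .poly_eval(coefficients, cols)
  d <- diff(wl)
  if (!(all(d > 0) || all(d < 0)))
    stop("dispersion_model: lambda(col) is not strictly monotone over col_range")
  m$wavelength_range <- range(wl)
  m
}

.poly_eval <- function(coef, x) {
  out <- numeric(length(x))
  for (k in rev(seq_along(coef))) out <- out * x + coef[k]
  out
}

#' Evaluate a dispersion model
#'
#' @param model a `dispersion_model`.
#' @param cols pixel columns; evaluating outside the valid range is an error.
#' @return wavelengths in nm.
#' @export
wavelength_at <- function(model, cols) {
  stopifnot(inherits(model, "dispersion_model"))
  tol <- 1e-9 * max(1, abs(model$col_range[2]))
  if (any(cols < model$col_range[1] - tol | cols > model$col_range[2] + tol))
    stop("wavelength_at: column outside the model's valid range [",
         model$col_range[1], ", ", model$col_range[2], "]")
  .poly_eval(model$coefficients, cols)
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat("Dispersion model: lambda(col) =",
      paste(format(x$coefficients, digits = 8),
            c("", "* col", paste0("* col^", seq_along(x$coefficients))[-(1:2)])[
              seq_along(x$coefficients)],
            collapse = " + "), "\n")
  cat("  valid columns ", x$col_range[1], "-", x$col_range[2],
      "  (", format(x$wavelength_range[1], digits = 6), "-",
      format(x$wavelength_range[2], digits = 6), " nm)\n", sep = "")
  if (!is.null(x$residuals_nm))
    cat("  fit residuals (nm):",
        paste(format(x$residuals_nm, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' Serialize a dispersion model to JSON
#'
#' @param model a `dispersion_model`.
#' @param path output file path.
#' @export
write_dispersion_json <- function(model, path) {
  stopifnot(inherits(model, "dispersion_model"))
  jsonlite::write_json(
    list(type = "dispersion_model",
         coefficients = model$coefficients,
         col_range = model$col_range,
         wavelength_range = model$wavelength_range,
         residuals_nm = model$residuals_nm),
    path, digits = NA, auto_unbox = FALSE, null = "null")
  invisible(path)
}

#' Read a dispersion model from JSON
#'
#' @param path JSON file written by [write_dispersion_json()].
#' @return a `dispersion_model`.
#' @export
read_dispersion_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$type) || x$type != "dispersion_model")
    stop("read_dispersion_json: ", path, " is not a dispersion model file")
  dispersion_model(x$coefficients, x$col_range,
                   residuals_nm = if (length(x$residuals_nm)) x$residuals_nm)
}
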