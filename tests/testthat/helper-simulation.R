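# Shared fixtures: a small, fast instrument covering 400-750 nm over 480
# columns (0.73 nm/column), built in code at test time.

test_dispersion <- function(cols = 480) {
  dispersion_model(c(400, 0.73), c(1, cols))
}

test_instrument <- function(rows = 16, cols = 480, ...) {
  instrument_model(dispersion = test_dispersion(cols),
                   sensor_rows = rows, sensor_cols = cols, ...)
}

noiseless_instrument <- function(rows = 16, cols = 480, ...) {
  test_instrument(rows = rows, cols = cols,
                  read_noise_sigma = 0, shot_noise_scale = 0, ...)
}

# lamp spectrum averaged over all rows and frames of a scan
lamp_spectrum <- function(scan) {
  acc <- Reduce(`+`, lapply(scan$frames, function(f)
    colMeans(f[, , 1] + f[, , 2] + f[, , 3])))
  acc / length(scan$frames)
}

# response curve from a simulated white reference under a known illuminant
white_response_curve <- function(model, illuminant = flat_illuminant(200),
                                 seed = 3, n_frames = 3,
                                 valid_window = c(400, 755)) {
  lib <- builtin_spectral_library()
  sc <- scene_map(matrix("white", n_frames, model$sensor_rows), lib, illuminant)
  cube <- assemble_cube(render_scan(sc, model, seed = seed), model$dispersion)
  idet <- extract_spectrum(cube, c(1, n_frames, 1, model$sensor_rows))
  istd <- data.frame(wavelength_nm = idet$wavelength_nm,
                     intensity = eval_spectrum(illuminant, idet$wavelength_nm))
  compute_response(istd, idet, valid_window = valid_window)
}
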