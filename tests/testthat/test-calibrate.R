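test_that("detect_peaks finds and refines isolated peaks", {
  y <- rep(0, 21); y[8:12] <- c(1, 2, 3, 2, 1)   # triangular peak at 10
  pk <- detect_peaks(y, 0.1)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$position, 10)
  expect_equal(pk$height, 3)

  # parabolic refinement recovers a sub-sample vertex
  x <- 1:31
  yq <- 5 - 0.1 * (x - 15.4)^2
  pk2 <- detect_peaks(yq, 0.1)
  expect_equal(pk2$position, 15.4, tolerance = 1e-9)

  expect_equal(nrow(detect_peaks(rep(2, 10), 0.5)), 0)   # flat: empty set
  expect_error(detect_peaks(c(1, 2), 0.1), "length")
  expect_error(detect_peaks(1:10, 0), "min_prominence_fraction")
})

test_that("detect_peaks applies the prominence threshold exactly", {
  # prominence oracle by construction:
  #   peak at 3 (height 5): key saddle 0    -> prominence 5.0 = 1.0 * range
  #   peak at 6 (height 4.5): key saddle 4  -> prominence 0.5 = 0.1 * range
  y <- c(0, 2.5, 5, 4, 4, 4.5, 4, 0)
  pk_hi <- detect_peaks(y, 0.5)
  expect_equal(nrow(pk_hi), 1)
  expect_lt(abs(pk_hi$position - 3), 0.6)
  pk_lo <- detect_peaks(y, 0.05)
  expect_equal(nrow(pk_lo), 2)
  expect_equal(pk_lo$prominence, c(5, 0.5))
})

test_that("detect_peaks resolves all 7 lamp lines on a noiseless render", {
  lib <- builtin_spectral_library()
  m0 <- noiseless_instrument(rows = 4, cols = 480)
  lamp <- scene_map(matrix("white", 1, 4), lib, mercury_lines(power = 160))
  spec <- lamp_spectrum(render_scan(lamp, m0, seed = 1))
  # min_separation merges quantization-staircase twin maxima on the
  # noiseless render (5 columns ~ 3.7 nm, far below the 16 nm line spacing)
  pk <- detect_peaks(spec, min_separation = 5)
  expect_equal(nrow(pk), 7)
  # brute-force local-maximum oracle on the same spectrum (plateau edges
  # count: quantization can flatten a maximum over two samples)
  i <- 2:(length(spec) - 1)
  brute <- i[spec[i] >= spec[i - 1] & spec[i] >= spec[i + 1] &
               (spec[i] > spec[i - 1] | spec[i] > spec[i + 1])]
  expect_true(all(vapply(pk$position, function(p)
    min(abs(brute - p)) < 1, TRUE)))
})

test_that("match_peaks pairs by rank and prunes spurious peaks", {
  refs <- mercury_lines()
  cols7 <- (refs$wavelength_nm - 400) / 0.39
  m <- match_peaks(cols7, refs)
  expect_equal(m$column, cols7)
  expect_equal(m$wavelength_nm, refs$wavelength_nm)

  # 8 detected, one spurious: exhaustive order-preserving oracle
  spurious <- sort(c(cols7, 333))
  m8 <- match_peaks(spurious, refs)
  expect_equal(nrow(m8), 7)
  expect_equal(m8$column, cols7)
  # independent exhaustive search over order-preserving subsets
  best <- NULL; best_ss <- Inf
  for (drop in seq_along(spurious)) {
    cc <- spurious[-drop]
    ss <- sum(stats::lm(refs$wavelength_nm ~ cc)$residuals^2)
    if (ss < best_ss) { best_ss <- ss; best <- cc }
  }
  expect_equal(m8$column, best)

  expect_error(match_peaks(5, refs), "at least 2")
  expect_error(match_peaks(c(2, 1, 3), refs), "strictly increasing")
})

test_that("fit_dispersion recovers known polynomials", {
  # exact line: zero residuals, coefficient recovery
  cols <- c(10, 100, 250, 400, 600, 750, 880)
  pairs <- data.frame(column = cols, wavelength_nm = 400 + 0.35 * cols)
  fit <- fit_dispersion(pairs, order = 1)
  expect_equal(fit$coefficients, c(400, 0.35), tolerance = 1e-10)
  expect_true(all(abs(fit$residuals_nm) < 1e-9))

  # exact quadratic recovered to 1e-6
  q <- c(398, 0.36, 2.5e-5)
  pairs2 <- data.frame(column = cols,
                       wavelength_nm = q[1] + q[2] * cols + q[3] * cols^2)
  fit2 <- fit_dispersion(pairs2, order = 2)
  expect_equal(fit2$coefficients, q, tolerance = 1e-6)

  expect_error(fit_dispersion(pairs[1:2, ], order = 2), "underdetermined")
  bad <- data.frame(column = c(1, 2, 3, 4),
                    wavelength_nm = c(400, 550, 560, 450))
  expect_error(fit_dispersion(bad, order = 2), "monotone|order")
})

test_that("dispersion model evaluation is range-checked and serializable", {
  d <- test_dispersion()
  expect_equal(wavelength_at(d, c(1, 480)), c(400.73, 750.4))
  expect_error(wavelength_at(d, 481), "outside")
  path <- tempfile(fileext = ".json")
  write_dispersion_json(d, path)
  d2 <- read_dispersion_json(path)
  expect_equal(d2$coefficients, d$coefficients)
  expect_equal(d2$col_range, d$col_range)
})

test_that("calibration_error_stats matches hand-computed cases", {
  s <- calibration_error_stats(c(1, 2), c(1.5, 2.5))
  expect_equal(c(s$min_nm, s$median_nm, s$max_nm), c(0.5, 0.5, 0.5))
  z <- calibration_error_stats(c(400, 500), c(400, 500))
  expect_equal(c(z$min_nm, z$median_nm, z$max_nm), c(0, 0, 0))
  expect_error(calibration_error_stats(1:3, 1:4), "mismatch")
  expect_error(calibration_error_stats(c(2, 1), c(1, 2)), "sorted")
})

test_that("error-stat ordering holds on random sorted inputs", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(1:9, 1)
    ref <- sort(stats::runif(n, 400, 700))
    meas <- sort(ref + stats::rnorm(n, 0, 0.5))
    s <- calibration_error_stats(meas, ref)
    expect_true(s$min_nm <= s$median_nm && s$median_nm <= s$max_nm)
    expect_true(all(s$errors_nm >= 0))
  }
})

test_that("compute_response implements I_std / I_det with guards", {
  wl <- seq(420, 640, by = 2)
  det <- data.frame(wavelength_nm = wl, intensity = 100 + wl / 10)
  # identical spectra: factor 1 on the valid mask
  r <- compute_response(det, det)
  expect_true(all(abs(r$factor[r$valid] - 1) < 1e-12))
  # detected twice the standard: factor 0.5
  det2 <- det; det2$intensity <- 2 * det$intensity
  r2 <- compute_response(det, det2)
  expect_true(all(abs(r2$factor[r2$valid] - 0.5) < 1e-12))
  # floor guard masks weak-signal wavelengths
  det3 <- det; det3$intensity[wl > 600] <- 0.01
  r3 <- compute_response(det, det3, floor_fraction = 0.05)
  expect_true(all(!r3$valid[wl > 600]))
  expect_error(
    compute_response(det, data.frame(wavelength_nm = wl + 900,
                                     intensity = det$intensity)),
    "overlap")
})

test_that("compute_response recovers the inverse channel sensitivity", {
  # LED seen through the instrument: I_det = LED * total response, so the
  # correction must match 1 / total response up to a global scale
  m <- noiseless_instrument(rows = 2, cols = 480)
  lib <- builtin_spectral_library()
  sig <- render_line_spectrum(lib$white, led_illuminant(200), m)
  wl <- attr(sig, "wavelength_nm")
  det <- data.frame(wavelength_nm = wl, intensity = rowSums(sig))
  std <- data.frame(wavelength_nm = wl, intensity = led_illuminant(200)(wl))
  r <- compute_response(std, det)
  expect_gt(sum(r$valid), 50)
  resp_total <- total_channel_response(m)(r$wavelength_nm[r$valid])
  a <- r$factor[r$valid] / mean(r$factor[r$valid])
  b <- (1 / resp_total) / mean(1 / resp_total)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("apply_response corrects, inverts and flags", {
  wl <- seq(420, 640, by = 2)
  std <- data.frame(wavelength_nm = wl, intensity = 50 + sin(wl / 40) * 10)
  det <- data.frame(wavelength_nm = wl,
                    intensity = std$intensity * (0.4 + 0.5 * exp(-(wl - 530)^2 / 8000)))
  curve <- compute_response(std, det)
  back <- apply_response(det, curve)
  i <- back$valid
  expect_true(any(i))
  expect_lt(max(abs(back$intensity[i] - std$intensity[i]) / std$intensity[i]),
            1e-9)
  # identity curve leaves the spectrum unchanged
  ident <- compute_response(det, det)
  same <- apply_response(det, ident)
  expect_equal(same$intensity[same$valid], det$intensity[same$valid])
  # masked-out bands come back flagged, not silently passed through
  det2 <- det; det2$intensity[wl > 600] <- 0.001
  curve2 <- compute_response(std, det2)
  out <- apply_response(det2, curve2)
  expect_true(all(is.na(out$intensity[wl > 610])))
  expect_true(all(!out$valid[wl > 610]))
  # JSON round trip
  path <- tempfile(fileext = ".json")
  write_response_json(curve, path)
  c2 <- read_response_json(path)
  expect_equal(c2$factor, curve$factor)
  expect_equal(c2$valid, curve$valid)
})
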