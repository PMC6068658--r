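test_that("hypercube validates its axis and data", {
  d <- array(1, dim = c(2, 3, 4))
  expect_error(hypercube(d, c(400, 410, 420)), "band count")
  expect_error(hypercube(d, c(400, 410, 405, 420)), "increasing")
  expect_error(hypercube(-d, 400 + 1:4), "negative")
  cube <- hypercube(d, 400 + 1:4)
  expect_equal(dim(cube), c(2, 3, 4))
  expect_true(all(cube$valid))
})

test_that("frame_to_line pools channels and bins columns into bands", {
  calib <- test_dispersion(100)   # 400.73 - 473.4 nm
  edges <- uniform_band_edges(401, 473, 36)
  # uniform gray frame: constant matrix
  fr <- array(5, dim = c(4, 100, 3))
  m <- frame_to_line(fr, calib, edges)
  expect_true(all(abs(m[, !is.na(m[1, ])] - 15) < 1e-12))

  # one bright column at ~550 nm: exactly one nonzero band, containing 550
  calib2 <- test_dispersion(480)
  edges2 <- uniform_band_edges(405, 745, 100)
  fr2 <- array(0, dim = c(2, 480, 3))
  col550 <- round((550 - 400) / 0.73)
  fr2[, col550, ] <- 10
  m2 <- frame_to_line(fr2, calib2, edges2)
  centers <- attr(m2, "wavelength_nm")
  nz <- which(m2[1, ] > 0)
  expect_length(nz, 1)
  expect_lt(abs(centers[nz] - 550), (745 - 405) / 100)

  expect_error(frame_to_line(fr2, calib2, uniform_band_edges(300, 900, 10)),
               "outside the calibrated range")
  expect_error(frame_to_line(array(0, c(2, 10)), calib, edges), "rows x cols")
})

test_that("frame_to_line matches the simulator ground truth at zero noise", {
  m0 <- noiseless_instrument(rows = 8, cols = 480)
  sc <- demo_scene(3, 8, 0.5)
  scan <- render_scan(sc, m0, seed = 1)
  line <- frame_to_line(scan$frames[[1]], m0$dispersion,
                        native_band_edges(m0$dispersion))
  truth <- scan$truth$data[1, , ]
  # worst-case deviation is half a DN per channel (round half up, 3 channels)
  expect_lte(max(abs(line - truth)), 1.5 + 1e-9)
  # and the overall deviation is below 1 % of the signal scale
  expect_lt(sqrt(mean((line - truth)^2)) / max(truth), 0.01)
})

test_that("assemble_cube stitches frames in scan order", {
  m0 <- noiseless_instrument(rows = 6, cols = 120)
  sc <- demo_scene(4, 6, 0.5)
  scan <- render_scan(sc, m0, seed = 2)
  cube <- assemble_cube(scan, m0$dispersion)
  expect_equal(dim(cube)[1], 4)

  single <- assemble_cube(scan$frames[1], m0$dispersion)
  expect_equal(dim(single)[1], 1)
  expect_equal(single$data[1, , ], cube$data[1, , ])

  # reversing the frame order mirrors the scan axis
  rev_cube <- assemble_cube(rev(scan$frames), m0$dispersion)
  expect_equal(rev_cube$data, cube$data[4:1, , ])

  bad <- scan$frames
  bad[[2]] <- array(0L, dim = c(5, 120, 3))
  expect_error(assemble_cube(bad, m0$dispersion), "frame 2")
  expect_error(assemble_cube(list(), m0$dispersion), "no frames")
})

test_that("cube assembly is frame-order equivariant", {
  m0 <- noiseless_instrument(rows = 5, cols = 100)
  sc <- demo_scene(5, 5, 0.4)
  scan <- render_scan(sc, m0, seed = 8)
  perm <- c(3, 1, 5, 2, 4)
  cube <- assemble_cube(scan$frames, m0$dispersion)
  cube_p <- assemble_cube(scan$frames[perm], m0$dispersion)
  expect_equal(cube_p$data, cube$data[perm, , ])
})

test_that("band_integrate sums half-open windows and is additive", {
  n_bands <- 50
  data <- array(1, dim = c(3, 4, n_bands))
  cube <- hypercube(data, seq(400.5, by = 1, length.out = n_bands))
  img <- band_integrate(cube, 400, 410)   # 10 centres in [400, 410)
  expect_true(all(img == 10))
  whole <- band_integrate(cube, 400, 451)
  expect_true(all(whole == n_bands))
  # additivity over a disjoint partition
  parts <- band_integrate(cube, 400, 417) + band_integrate(cube, 417, 433) +
    band_integrate(cube, 433, 451)
  expect_equal(parts, whole)
  expect_error(band_integrate(cube, 900, 950), "no valid band")
  expect_error(band_integrate(cube, 500, 450), "lo_nm < hi_nm")
})

test_that("extract_spectrum averages regions and checks bounds", {
  set.seed(5)
  data <- array(stats::runif(2 * 3 * 6), dim = c(2, 3, 6))
  cube <- hypercube(data, 500 + 1:6)
  one <- extract_spectrum(cube, c(2, 2, 3, 3))
  expect_equal(one$intensity, data[2, 3, ])
  all_px <- extract_spectrum(cube, c(1, 2, 1, 3))
  expect_equal(all_px$intensity, apply(data, 3, mean))
  expect_identical(attr(all_px, "n_pixels"), 6L)
  expect_error(extract_spectrum(cube, c(1, 2, 1, 9)), "out of bounds")
  expect_error(extract_spectrum(cube, c(2, 1, 1, 3)), "empty")
})

test_that("homogeneous region spectra match the library shape", {
  m0 <- noiseless_instrument(rows = 6, cols = 480)
  lib <- builtin_spectral_library()
  sc <- scene_map(matrix("vegetation", 2, 6), lib, flat_illuminant(200))
  cube <- assemble_cube(render_scan(sc, m0, seed = 3), m0$dispersion)
  sp <- extract_spectrum(cube, c(1, 2, 1, 6))
  truth <- eval_spectrum(lib$vegetation, sp$wavelength_nm) *
    200 * total_channel_response(m0)(sp$wavelength_nm)
  cosine <- sum(sp$intensity * truth) /
    sqrt(sum(sp$intensity^2) * sum(truth^2))
  expect_gt(cosine, 0.99)
})

test_that("profile_fwhm matches closed-form widths", {
  # Gaussian trough: FWHM = 2.3548 sigma within 2 % at fine sampling
  x <- seq(0, 60, by = 0.05)
  for (sigma in c(1.5, 3, 5)) {
    y <- 1 - 0.8 * exp(-(x - 30)^2 / (2 * sigma^2))
    f <- profile_fwhm(x, y)
    expect_equal(f$feature, "trough")
    expect_lt(abs(f$fwhm - 2.3548 * sigma) / (2.3548 * sigma), 0.02)
  }
  # rectangular trough of width w (w samples at spacing dx): FWHM = w
  y2 <- rep(1, 100); y2[41:60] <- 0
  f2 <- profile_fwhm(1:100, y2)
  expect_equal(f2$fwhm, 20)
  # mm scaling is multiplicative
  f2mm <- profile_fwhm(1:100, y2, scale = 0.31)
  expect_equal(f2mm$fwhm, 20 * 0.31)
  # bright peak features work symmetrically
  y3 <- rep(0.2, 100); y3[46:55] <- 1
  expect_equal(profile_fwhm(1:100, y3)$feature, "peak")
})

test_that("profile_fwhm rejects degenerate profiles", {
  expect_error(profile_fwhm(1:50, seq(0, 1, length.out = 50)), "clipped")
  expect_error(profile_fwhm(1:10, rep(1, 10)), "no feature")
  y <- rep(1, 20); y[1:5] <- 0   # trough clipped at the left edge
  expect_error(profile_fwhm(1:20, y), "clipped")
  expect_error(profile_fwhm(c(1, 3, 2), c(1, 2, 1)), "ascending")
})
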