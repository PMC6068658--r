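#' Build a demonstration scene with a planted vegetation fraction
#'
#' A scene whose pixels are vegetation for an exactly known fraction of the
#' (scan line x slit row) grid - the ground truth against which RLRI
#' coverage recovery is checked - and a neutral building surface elsewhere.
#' Vegetation fills whole scan lines first, then a partial line, so the
#' planted fraction is exact to one pixel.
#'
#' @param n_scan_lines,slit_rows scene dimensions.
#' @param vegetation_fraction fraction of pixels labelled vegetation.
#' @param library spectral library (default [builtin_spectral_library()]).
#' @param illuminant scene illuminant.
#' @return a `scene_map` with attribute `vegetation_fraction` (the exact
#'   planted fraction).
#' @export
demo_scene <- function(n_scan_lines, slit_rows, vegetation_fraction = 1 / 3,
                       library = builtin_spectral_library(),
                       illuminant = flat_illuminant()) {
  n <- n_scan_lines * slit_rows
  k <- round(vegetation_fraction * n)
  labels <- matrix("building", n_scan_lines, slit_rows)
  if (k > 0) {
    flat <- as.vector(t(labels))      # scan-major order
    flat[seq_len(k)] <- "vegetation"
    labels <- matrix(flat, n_scan_lines, slit_rows, byrow = TRUE)
  }
  sc <- scene_map(labels, library, illuminant)
  attr(sc, "vegetation_fraction") <- k / n
  sc
}

#' Validate a pipeline run configuration
#'
#' Fills defaults and checks that every referenced input path exists before
#' any computation starts.
#'
#' @param config named list, or path to a YAML/JSON config file.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("run_config: no such config file: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    output_dir = "pushbroom_out",
    seed = 1L,
    simulate = list(enabled = TRUE, sensor_rows = 32, sensor_cols = 480,
                    scan_lines = 48, vegetation_fraction = 1 / 3,
                    dispersion = c(400, 0.73), n_lamp_frames = 3),
    calibrate = list(lamp_frames = NULL, lines_csv = NULL, order = 1),
    cube = list(frames = NULL),
    analyze = list(threshold = 0.3, nir_window = c(740, 750),
                   red_window = c(680, 690))
  )
  cfg <- utils::modifyList(defaults, config)
  sim <- isTRUE(cfg$simulate$enabled)
  if (!sim) {
    if (is.null(cfg$calibrate$lamp_frames) || is.null(cfg$cube$frames))
      stop("run_config: with simulation disabled, calibrate$lamp_frames ",
           "and cube$frames must both be given")
    for (p in c(cfg$calibrate$lamp_frames, cfg$cube$frames))
      if (!dir.exists(p)) stop("run_config: input path does not exist: ", p)
  }
  if (!is.null(cfg$calibrate$lines_csv) && !file.exists(cfg$calibrate$lines_csv))
    stop("run_config: reference line table does not exist: ",
         cfg$calibrate$lines_csv)
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full push-broom pipeline
#'
#' Executes (optionally) simulate, then wavelength calibration from lamp
#' frames, cube assembly from the scene frames, and RLRI analysis; writes
#' all intermediates (calibration JSON, ENVI cube, spatial image, RLRI
#' overlay PNG, coverage JSON) plus an output manifest with checksums. The
#' run is deterministic for a fixed config and seed.
#'
#' @param config a `run_config`, a plain list, or a config file path.
#' @return an `output_manifest` (invisibly contains the coverage fraction
#'   in `$results$coverage`).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  stage <- "simulate"
  result <- tryCatch({
    lamp_dir <- cfg$calibrate$lamp_frames
    scene_dir <- cfg$cube$frames
    truth_disp <- NULL
    if (isTRUE(cfg$simulate$enabled)) {
      s <- cfg$simulate
      truth_disp <- dispersion_model(as.numeric(s$dispersion),
                                     c(1, s$sensor_cols))
      model <- instrument_model(dispersion = truth_disp,
                                sensor_rows = s$sensor_rows,
                                sensor_cols = s$sensor_cols)
      lib <- builtin_spectral_library()
      lamp <- scene_map(matrix("white", s$n_lamp_frames, s$sensor_rows),
                        lib, mercury_lines(power = 160))
      lamp_scan <- render_scan(lamp, model, seed = cfg$seed)
      lamp_dir <- file.path(out, "lamp_frames")
      write_frames(lamp_scan, lamp_dir)
      scene <- demo_scene(s$scan_lines, s$sensor_rows, s$vegetation_fraction)
      scene_scan <- render_scan(scene, model, seed = cfg$seed + 1L)
      scene_dir <- file.path(out, "scene_frames")
      write_frames(scene_scan, scene_dir)
    }

    stage <- "calibrate"
    lamp_frames <- read_frames(lamp_dir)
    mid <- lamp_frames$frames[[ceiling(length(lamp_frames) / 2)]]
    lamp_spec <- colMeans(mid[, , 1] + mid[, , 2] + mid[, , 3])
    ref <- if (is.null(cfg$calibrate$lines_csv)) mercury_lines()
    else emission_lines(read_spectrum_csv(cfg$calibrate$lines_csv)$wavelength_nm,
                        read_spectrum_csv(cfg$calibrate$lines_csv)$intensity)
    peaks <- detect_peaks(lamp_spec, min_separation = 5)
    calib <- fit_dispersion(match_peaks(peaks, ref),
                            order = cfg$calibrate$order,
                            col_range = c(1, length(lamp_spec)))
    calib_path <- file.path(out, "calibration.json")
    write_dispersion_json(calib, calib_path)

    stage <- "assemble"
    scene_frames <- read_frames(scene_dir)
    cube <- assemble_cube(scene_frames, calib)
    cube_path <- file.path(out, "cube")
    write_cube_envi(cube, cube_path)

    stage <- "analyze"
    wl <- cube$wavelength_nm[cube$valid]
    spatial <- band_integrate(cube, min(wl), max(wl) + 1e-9)
    index <- rlri(cube, as.numeric(cfg$analyze$nir_window),
                  as.numeric(cfg$analyze$red_window))
    mask <- threshold_mask(index, cfg$analyze$threshold)
    ov <- overlay(spatial, mask)
    overlay_path <- file.path(out, "rlri_overlay.png")
    png::writePNG(ov, overlay_path)
    coverage_path <- file.path(out, "coverage.json")
    jsonlite::write_json(list(coverage = mask$coverage,
                              threshold = mask$threshold,
                              n_valid = mask$n_valid),
                         coverage_path, auto_unbox = TRUE, digits = NA)
    list(calib = calib, coverage = mask$coverage,
         files = c(calib_path, paste0(cube_path, ".img"),
                   paste0(cube_path, ".hdr"), overlay_path, coverage_path))
  }, error = function(e) {
    stop("run_pipeline: stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  files <- result$files
  manifest <- structure(list(
    tool = "pushbroomr",
    version = as.character(utils::packageVersion("pushbroomr")),
    config_hash = digest::digest(unclass(cfg)),
    seed = cfg$seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(threshold = cfg$analyze$threshold,
                      nir_window = cfg$analyze$nir_window,
                      red_window = cfg$analyze$red_window,
                      fit_order = cfg$calibrate$order),
    results = list(coverage = result$coverage),
    artifacts = lapply(files, function(f)
      list(path = f, md5 = digest::digest(file = f, algo = "md5")))
  ), class = "output_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @export
print.output_manifest <- function(x, ...) {
  cat("Pipeline manifest (", x$tool, " ", x$version, ", seed ", x$seed, ")\n",
      sep = "")
  cat("  coverage:", format(100 * x$results$coverage, digits = 4), "%\n")
  cat("  artifacts:\n")
  for (a in x$artifacts) cat("   ", a$path, " md5:", a$md5, "\n")
  invisible(x)
}
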