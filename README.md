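# pushbroomr

Software stack for compact push-broom (slit-scan) imaging spectrometers
built from consumer cameras. One video frame of such an instrument holds a
dispersed image of a single scene line — horizontal axis spectral,
vertical axis spatial — and sweeping the view direction stacks frames into
a hyperspectral cube (two spatial axes, one spectral axis, roughly
400–750 nm at ~15 nm resolution for the instrument class this targets).

The package is aimed at instrument builders and analysts in environmental
and biomedical sensing who need the full processing chain without the
hardware in hand:

* **Forward simulator** — scene reflectance → illuminated radiance →
  dispersed, colour-filtered, noisy, quantized frame sequence, with the
  ground-truth cube kept alongside (`instrument_model()`, `scene_map()`,
  `render_scan()`, `builtin_spectral_library()`).
* **Wavelength calibration** — mercury-lamp peak detection with sub-pixel
  parabolic refinement, order-preserving peak↔line matching, polynomial
  dispersion fit λ(col), and per-line error statistics
  (`detect_peaks()`, `match_peaks()`, `fit_dispersion()`,
  `calibration_error_stats()`).
* **Radiometric response correction** — factor(λ) = I_std(λ)/I_det(λ)
  from a reference spectrometer measurement, with a signal floor and
  validity mask (`compute_response()`, `apply_response()`).
* **Cube assembly** — RGB channel pooling, column→band binning on a
  calibrated wavelength grid, ENVI (BSQ + text header) I/O, band-integrated
  spatial imagery, region spectra, FWHM spatial-resolution profiling
  (`assemble_cube()`, `band_integrate()`, `extract_spectrum()`,
  `profile_fwhm()`, `write_cube_envi()`).
* **Analyses** — the reflected light ratio index
  RLRI = (NIR − RED)/(NIR + RED) with NIR = 740–750 nm and
  RED = 680–690 nm band integrals (an in-range NDVI substitute for sensors
  that stop at 750 nm), 0.3-threshold vegetation masks with coverage
  fractions, red/blue mask overlays, absorption-trough detection
  (oxyhemoglobin 419/573 nm, chlorophyll ~650 nm) and 550 nm
  normalisation (`rlri()`, `threshold_mask()`, `overlay()`,
  `find_troughs()`, `normalize_at()`).

## Worked example

```r
library(pushbroomr)

# an instrument whose grating maps column -> 400 + 0.73*col nm
model <- instrument_model(
  dispersion = dispersion_model(c(400, 0.73), c(1, 480)),
  sensor_rows = 24, sensor_cols = 480)

# a scene with exactly one third vegetation, the rest neutral building
scene <- demo_scene(30, 24, vegetation_fraction = 1/3)
scan  <- render_scan(scene, model, seed = 42)    # 30 frames + ground truth

cube <- assemble_cube(scan, model$dispersion)
cube
#> Hypercube: 30 scan lines x 24 slit rows x 480 bands (400.73-750.4 nm), 480 valid bands

mask <- threshold_mask(rlri(cube), threshold = 0.3)
mask
#> Binary mask 30 x 24, threshold 0.3: coverage 33.33% of 720 valid pixels
```

The printed coverage is the planted vegetation fraction recovered through
the whole chain (simulate → assemble → index → threshold): vegetation
pixels score RLRI ≈ 0.7–0.8 (strong 740–750 nm reflectance, chlorophyll
absorption at 680–690 nm) and building pixels ≈ −0.07, so the 0.3
threshold separates them cleanly at the default noise level.

The same flow driven by a config file, including wavelength calibration
from simulated mercury-lamp frames, a JSON calibration file, an ENVI cube
and a checksummed run manifest:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "pushbroomr"))
#> Pipeline manifest (pushbroomr 0.1.0, seed 42)
#>   coverage: 33.33 %
#>   artifacts:
#>     pushbroom_out/calibration.json ...
#>     pushbroom_out/cube.img ...
```

A command-line wrapper for each stage ships at
`system.file("cli", "pushbroom.R", package = "pushbroomr")`:

```sh
Rscript inst/cli/pushbroom.R run --config inst/extdata/demo_config.yaml
Rscript inst/cli/pushbroom.R calibrate-wavelength \
  --frames pushbroom_out/lamp_frames --lines inst/extdata/hg_lines.csv \
  --order 1 --out calib.json
```

## Documentation

The methods vignette (`vignettes/pushbroomr-methods.Rmd`) describes the
forward model and its assumptions, every tunable parameter with units and
defaults, what the synthetic scenes do and do not establish, and the
numerical choices (quantization, tie-breaks, masking, degenerate inputs).
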