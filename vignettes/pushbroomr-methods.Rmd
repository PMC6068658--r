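---
title: "Push-broom imaging spectrometry with pushbroomr: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Push-broom imaging spectrometry with pushbroomr: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pushbroomr)
```

## The instrument and its computational model

A push-broom (slit-scan) imaging spectrometer images one spatial line of a
scene at a time. Light from that line passes a slit, is collimated,
dispersed by a grating-prism pair and lands on a colour CMOS sensor: each
video frame therefore has a *spectral* horizontal axis and a *spatial*
vertical axis. Sweeping the view direction (a motorised mount) and stacking
frames yields a hyperspectral cube with two spatial axes and one spectral
axis. Low-cost builds of this design reach roughly 400-750 nm with a
spectral resolution near 15 nm and a 1920 x 1080, 8-bit sensor.

`pushbroomr` implements the full software stack for such an instrument:

* a forward simulator (`instrument_model()`, `render_scan()`) that provides
  ground-truthed inputs for every downstream stage;
* wavelength calibration from a mercury-lamp exposure
  (`detect_peaks()`, `match_peaks()`, `fit_dispersion()`) and radiometric
  response correction (`compute_response()`, `apply_response()`);
* cube assembly (`frame_to_line()`, `assemble_cube()`) plus band
  integration, region spectra and FWHM profiling;
* the downstream analyses: RLRI vegetation mapping with coverage
  (`rlri()`, `threshold_mask()`), absorption-trough detection
  (`find_troughs()`), and 550 nm normalisation (`normalize_at()`).

## Forward model

For a sensor column `col`, the ground-truth dispersion polynomial gives the
wavelength $\lambda(\mathrm{col}) = c_0 + c_1\,\mathrm{col} +
c_2\,\mathrm{col}^2$. Grating dispersion is near-linear; the optional
quadratic term exists to exercise the calibration fit. The noiseless signal
in channel $ch$ is

$$ S(\mathrm{col}, ch) = E(\lambda)\, R(\lambda)\, Q_{ch}(\lambda), $$

with $E$ the illuminant spectral power (in DN-scale units), $R$ the scene
reflectance and $Q_{ch}$ the channel sensitivity. Frames are produced from
$S$ by an optional Gaussian slit-PSF blur along the spatial axis, additive
Gaussian read noise (default sigma 2 DN), signal-scaled noise with standard
deviation $0.5\sqrt{S}$ (a shot-noise surrogate on the DN scale), and
quantization by rounding half-up to the sensor bit depth (default 8). An
optional per-frame global gain jitter models an auto-ISO camera; it is off
by default, mirroring the practical advice to scan scenes with only slight
intensity variation when the camera's ISO cannot be fixed.

The ground-truth cube stored alongside the frames holds the noiseless,
unblurred panchromatic (R+G+B) signal on the native wavelength axis; the
zero-noise reconstruction round trip is therefore exact up to quantization
(at most 0.5 DN per channel, 1.5 DN after channel summing).

### Channel sensitivities

Blue and green channels are Gaussians centred at 460 and 535 nm (sigmas 40
and 45 nm). The red channel is a sigmoid plateau from about 600 nm to
750 nm: a consumer sensor only reaches the 740-750 nm vegetation band when
its infrared-cut filter is removed, and the silicon response there is broad
and flat rather than band-like. Two consequences of this realistic shape
matter for analysis and are demonstrated by the tests:

* the *blue roll-off* suppresses the DN signal below ~430 nm, and
* the *G/R crossover* leaves a shallow sensitivity dip near 570 nm.

### Emission-line rendering

Lamp lines are rendered as Gaussians peaking at the line's relative
intensity. The default sigma is 5.5 nm (FWHM about 13 nm). A strict 15 nm
FWHM would merge the 578.9/595.3 nm lamp pair (16.4 nm apart) into a single
peak, while the physical instrument this models demonstrably resolves all
seven lamp lines; 13 nm keeps the stated "about 15 nm" resolution while
preserving that observable. Mercury-lamp relative intensities are not
published as part of the lamp peak lists, so nominal values (0.55, 0.80,
1.00, 0.75, 0.50, 0.85, 0.30) were fixed once; they resemble a
fluorescent-lamp spectrum with a strong green line and a strong red
phosphor line.

### Builtin reflectance library

`builtin_spectral_library()` provides idealised materials on a 1 nm grid:
vegetation (reflectance ~0.08 at 680-690 nm rising to ~0.6 by 740-750 nm -
the chlorophyll red edge), a neutral building surface (0.35 flat), lip and
cheek skin (multiplicative Gaussian troughs at 419 nm, the oxyhemoglobin
Soret band, and 573 nm; the cheek's 573 nm trough is configured shallower
because cheek tissue is less blood-rich), green banana skin (chlorophyll
trough at 650 nm) and ripe banana skin (no 650 nm feature), plus a white
reference. These are *stated worlds*, not measured spectra: they reproduce
the qualitative features the analyses target (trough positions, red edge,
index contrast) but not the absolute reflectance of any real material, so a
green test establishes that the pipeline recovers what the generator
planted - not that it would quantitatively match a field measurement.

## Wavelength calibration

`detect_peaks()` finds local maxima whose topographic prominence is at
least a fraction (default 0.05) of the spectrum's dynamic range and refines
positions by parabolic interpolation through the maximum and its two
neighbours - at ~0.4-0.7 nm per column, sub-0.5 nm wavelength accuracy
requires sub-pixel positions. A `min_separation` floor (used at 5 columns
by the calibration flows) merges twin maxima that 8-bit quantization can
carve out of a single line; nothing physical can be narrower than the
instrument linewidth, so this suppresses only artifacts.

`match_peaks()` pairs detected columns with reference wavelengths by rank
when the counts agree; otherwise it exhaustively searches order-preserving
subsets of the longer list and keeps the one minimising the summed squared
residuals of a provisional linear fit - robust to one or two spurious
detections. `fit_dispersion()` is an ordinary least-squares polynomial fit
(order 1 by default, order 2 supported; seven lines determine a stable
quadratic but linear is the safe default), verified to be strictly
monotone over its declared column range. The declared range may be widened
to the full sensor so that bands beyond the outermost lamp line (e.g.
740-750 nm, past the 699.2 nm line) remain usable; this is a mild
extrapolation of a near-linear mapping and is the package's deliberate
choice.

`calibration_error_stats()` summarises per-line absolute errors by
min/median/max, with the even-count median defined as the mean of the two
central values. Fed with the published pair of seven-line peak lists it
returns 0.1 / 0.3 / 1.4 nm; note the published maximum for those same lists
(0.9 nm) is not reproducible from the lists themselves, so only the
minimum and median are treated as checkable.

## Response correction

The relative intensity response is estimated as
$\mathrm{factor}(\lambda) = I_{std}(\lambda) / I_{det}(\lambda)$ from a
common source measured by a trusted spectrometer ($I_{std}$) and by this
instrument ($I_{det}$). The ratio diverges where the detector signal
vanishes, so the factor is masked where $I_{det}$ falls below a floor
(default 5 % of its maximum) or outside a validity window (default
400-650 nm, matching what an LED source supports; the simulator's white
reference under a flat illuminant supports the full 400-755 nm and tests
pass a wider window accordingly). `apply_response()` multiplies on the
valid mask and returns `NA` elsewhere - masked bands are flagged, never
silently passed through.

Correction matters for feature detection: on raw DN spectra the blue
roll-off hides the 419 nm Soret trough (the dip is a few DN against a
~300 DN dynamic range) and the G/R crossover dip near 570 nm appears as a
"trough" in every material. The trough analyses therefore run on
response-corrected spectra; this mirrors the instrument's own calibration
recipe, which states the response spectrum is used to calibrate the data.

## Cube assembly and analyses

`frame_to_line()` pools the three colour channels by an unweighted sum
(the simplest monotone pooling, and exactly the simulator's forward
model), maps columns to wavelengths through the calibration and averages
contributing columns into half-open wavelength bands $[\mathrm{lo},
\mathrm{hi})$; half-open windows make integrals over a partition add up
exactly. The default band grid is the native one-band-per-column grid
(~0.4-0.7 nm spacing, i.e. on the order of 900 bands over 400-750 nm).
Bands receiving no column are marked invalid and excluded from integrals.

`rlri()` computes the reflected light ratio index
$(\mathrm{NIR}-\mathrm{RED})/(\mathrm{NIR}+\mathrm{RED})$ with NIR the
band-integrated signal over 740-750 nm and RED over 680-690 nm - an
in-range substitute for NDVI on an instrument whose sensitivity ends at
750 nm (NDVI's 800 nm band is unreachable, and NDVI is deliberately not
implemented). Sums rather than means are integrated; because the index is
a normalised ratio the choice is immaterial when both windows hold equal
band counts, which the tests assert. The index is computed on raw DN
spectra (the illuminant and response cancel to first order in the ratio);
pixels with $\mathrm{NIR}+\mathrm{RED}=0$ are masked. `threshold_mask()`
uses a strict "greater than" at the default threshold 0.3 - a pixel at
exactly 0.3 is not vegetation - and reports coverage as set/valid pixels
(invalid pixels are excluded from the denominator; the alternative -
counting all pixels - was rejected because masked pixels carry no
evidence either way).

`find_troughs()` negates the spectrum, smooths with a moving average of a
stated wavelength window (default 10 nm; shrinking symmetric windows at
the edges), and reuses the peak detector, so a trough's depth is its
topographic prominence relative to the smoothed spectrum itself - no
separate continuum-removal step is imposed, because none is defined for
this instrument class. `normalize_at()` divides by the linearly
interpolated value at an anchor (550 nm by convention) so spectra of
differently lit objects compare shape-to-shape.

`profile_fwhm()` measures spatial resolution: the baseline is the profile
median, the feature is the global extremum farther from the baseline
(trough or peak), the half level is midway between them, and crossings are
linearly interpolated on both sides of the extremum. A profile whose
feature touches the profile edge is rejected as clipped. The pixel-to-mm
scale must be supplied by the user - it depends on working distance and
magnification, which the software cannot infer.

## Numerical choices and degenerate inputs

* Quantization rounds half-up; noise is applied after blur, before
  quantization.
* A flat spectrum yields an empty peak set (not an error); a monotone
  profile is a clipped-feature error in `profile_fwhm()`.
* `calibration_error_stats()` requires both line lists sorted ascending -
  the pairing is positional, and silently accepting unsorted input would
  pair wrong lines.
* Ties at the RLRI threshold go to non-vegetation (strict inequality).
* ENVI output is BSQ, little-endian IEEE doubles (data type 5), with the
  wavelength axis written at 17 significant digits, so integer and float
  cubes round-trip bit-exactly. Band validity is carried in an auxiliary
  header entry.
* 8-bit frames are PNG; higher bit depths are stored as binary 16-bit PPM
  (P6) because no available PNG writer emits 16-bit samples. DN values are
  preserved exactly in both containers, and the frame manifest records the
  true bit depth.

## What the synthetic world does not establish

The simulator omits geometric optics (aberrations, prism deflection,
keystone/smile), motion blur and scan distortion from platform shake,
spatially varying illumination, and spectrally correlated sensor noise.
Materials are smooth idealisations. Consequently, green acceptance tests
demonstrate internal consistency of the pipeline - calibration recovery,
coverage recovery to +/- 0.02, trough recovery to +/- 5 nm, the FWHM
closed form to 2 % - under the stated noise model, not field performance.
The published field figures (a 33.76 % vegetation coverage of one campus
scene, 5.9/6.8 mm FWHM at 65 cm) depend on unpublished videos and are not
desk-reproducible; the package's analogue checks plant known fractions and
known profiles instead.

## A worked example

```{r example, eval = FALSE}
model <- instrument_model(
  dispersion = dispersion_model(c(400, 0.73), c(1, 480)),
  sensor_rows = 24, sensor_cols = 480)
scene <- demo_scene(30, 24, vegetation_fraction = 1 / 3)
scan <- render_scan(scene, model, seed = 42)
cube <- assemble_cube(scan, model$dispersion)
mask <- threshold_mask(rlri(cube), threshold = 0.3)
mask$coverage   # ~0.333: the planted third, recovered through the stack
```

The same flow, driven by a config file and with wavelength calibration
performed from simulated lamp frames rather than taken from ground truth,
is `run_pipeline(system.file("extdata", "demo_config.yaml",
package = "pushbroomr"))`.
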