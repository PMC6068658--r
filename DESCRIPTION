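Package: pushbroomr
Title: Push-Broom Imaging Spectrometer Simulation, Calibration and Analysis
Version: 0.1.0
Authors@R: person("pushbroomr", "developers", role = c("aut", "cre"),
    email = "pushbroomr@example.org")
Description: Tools for slit-scan (push-broom) imaging spectrometers built
    from consumer cameras: a forward simulator of the dispersing optics and
    CMOS sensor, mercury-lamp wavelength calibration with sub-pixel peak
    detection, radiometric response correction, hyperspectral cube assembly
    from frame sequences, and downstream spectral analyses including the
    reflected light ratio index (RLRI) for vegetation mapping, absorption
    trough detection for chlorophyll and oxyhemoglobin features, and FWHM
    spatial-resolution estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    yaml,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
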