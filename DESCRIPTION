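Package: duohct
Title: Dual-Isotope Autoradiography Mapping of Tissue Hematocrit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and quantification pipeline for dual-isotope
    (99mTc-labelled red blood cells plus 125I-labelled albumin)
    phosphor-imager autoradiography of tissue hematocrit. Provides a
    physics-faithful simulator of paired exposures of brain-like
    cryosection phantoms with internal reference spots, separation of the
    two isotope signals from sequential exposures, photostimulated
    luminescence calibration against a diluted-blood standard, per-pixel
    plasma, red-blood-cell and vascular distribution-volume maps with
    derived tissue hematocrit, a gamma-well-counting scalar path, and
    region-of-interest statistics including agreement fits and
    hematocrit histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
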