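Package: roGFPtools
Title: Quantification of Ratiometric roGFP Redox Biosensor Measurements
Version: 0.1.0
Authors@R:
    person("ER redox imaging contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Quantification pipeline for ratiometric roGFP-family redox
    biosensors targeted to the endoplasmic reticulum lumen: degree-of-oxidation
    and Nernst conversions between fluorescence ratios, sensor oxidation, and
    glutathione redox potentials; pixel-wise ratio imaging of two-channel
    confocal data with background, autofluorescence bleed-through and spatial
    averaging corrections; plate-reader and perfusion time-series analysis with
    phase segmentation, steady-state/peak/recovery features and linear
    reduction and re-oxidation rates; weighted hypoxia survival scores; and
    synthetic-data generators with ground truth (ER-network images under a
    two-state spectral mixing model, and a minimal ODE model of luminal
    glutathione-pool redox dynamics under hypoxia-reoxygenation schedules).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
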