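Package: neurotube
Title: Biomechanics of Neural Tube Shape Divergence: Creep Rheology,
    Pressurized-Tube Simulation and Tissue-Shape Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the biomechanics of epithelial tube
    morphogenesis, built around the early chicken neural tube. Fits
    power-law viscoelastic creep models to atomic force microscopy
    indentation experiments in two stages (force-ramp shape, then
    creep compliance), with an independent hereditary-integral oracle
    and a Hertz instantaneous fit. Simulates a pressurized thin-shell
    tube of Maxwell viscoelastic tissue with an angular material
    pre-pattern, and inverts ferrofluid-droplet rounding dynamics for
    tissue viscosity. Quantifies cross-section shape via
    circumferential thickness profiles with dorsal/ventral
    normalisation, roof metrics and apical intensity binning, and runs
    the accompanying small-cohort statistics. A synthetic-data module
    generates every input with known ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
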