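Package: adaptqa
Title: Plan Quality Evaluation for MR-Guided Adaptive Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing adapt-to-shape workflows on MR-guided linear
    accelerators without patient data. Provides a voxel-grid data model with
    polygon rasterization and anisotropic morphology (margin expansion,
    depth-limited trimming, plane cropping), adapters for DICOM RT Structure
    Set and RT Dose files plus a portable fraction-bundle archive, a synthetic
    pelvic phantom with per-fraction organ deformation and per-observer
    contour noise calibrated to a target Dice index, Boolean target-generation
    rules (bladder depth trim, bowel subtraction, PTV margin), a dose-volume
    histogram engine (Dmean, Dmax, Dx%, D(v cc)) with the RTOG conformity
    index, tiered dose-constraint classification with ideal and
    acceptable-variation limits, gold-standard overlay re-evaluation, and
    workflow safety-rate aggregation with outcome heat maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
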