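Package: octdamage
Title: Quantification of Laser-Induced Skin Damage from OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for quantifying laser-induced skin damage in swept-source
    optical coherence tomography (OCT) B-scan stacks. Provides block-matching
    collaborative-filtering (BM3D-style) speckle suppression with frequency-
    domain diagnostics, UNet semantic segmentation of damaged-skin regions with
    parameter-free energy attention (SimAM) and pyramid squeeze attention (PSA)
    combined in tandem, parallel and nested topologies, the standard
    segmentation metrics (Dice, accuracy, mean pixel accuracy, mean IoU) on a
    confusion-matrix substrate, and voxel-based damage-volume estimation across
    dose and recovery-time groups. A seeded synthetic phantom generator
    emulating layered skin-like OCT cross-sections with elliptical lesions
    makes the whole pipeline testable without any acquired data. Includes a
    small reverse-mode automatic-differentiation engine with compiled
    convolution kernels so the networks train on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
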