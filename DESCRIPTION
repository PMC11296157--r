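Package: foramcurve
Title: Training-Set Sufficiency Analysis for 3D Segmentation of Foraminifera Micro-CT
Version: 0.1.0
Authors@R:
    person("Foramcurve", "Developers", email = "foramcurve@example.org",
           role = c("aut", "cre"))
Description: Desk-scale pipeline for studying how many manually segmented
    specimens are needed to train an accurate volumetric segmentation
    network for chambered microfossil shells. Provides a synthetic phantom
    generator for foraminifera-like micro-CT volumes with paired
    three-label segmentations (background, external calcite wall, internal
    chamber space), axis-permutation data augmentation, a small patch-based
    3D U-Net trained by stochastic gradient descent with early stopping and
    replicate-median selection, multi-label Dice and volumetric trait
    evaluation, mesh-based shape scores via surface alignment and kernel
    PCA, and learning-curve statistics (quasibinomial Dice GLM,
    manual-versus-network agreement regressions, minimum-specimen
    estimation).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
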