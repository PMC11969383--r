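Package: cellcyclekit
Title: Cell Cycle Staging from 3D Nuclear-Stain Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting cell cycle stage (G1 versus S/G2) from 3D
    DAPI-stained single-nucleus image volumes. Provides Fucci-reporter-based
    ground-truth labeling with low-intensity, ratio and volume exclusion
    filters; per-nucleus quality control and 3D morphometry (integrated
    intensity, volume, convex volume, surface area, sphericity, Feret
    diameter); 2D/3D support-vector-machine baselines with nested
    cross-validation; a volumetric convolutional classifier and continuous
    cell-cycle angle regressor trained with Adam; and a deterministic
    synthetic Fucci image simulator that renders multi-channel tiles with
    instance masks and per-nucleus truth so the whole pipeline is testable
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    tiff,
    jsonlite,
    e1071
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
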