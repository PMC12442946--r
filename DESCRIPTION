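Package: pancus
Title: Pancreatic Ultrasound Texture Biomarkers and Therapeutic Ultrasound Thermal Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of masked B-mode ultrasound images of
    the pancreas and for patient-geometry-informed therapeutic ultrasound planning.
    Provides a seeded speckle-phantom generator for class-labelled synthetic cohorts,
    morphology and texture feature extraction (gray-level co-occurrence matrix
    Haralick statistics, local binary patterns, intensity entropy, Sobel gradients,
    scale-space keypoint counts), univariate biomarker screening (pooled t-test gate,
    Spearman rank correlation, k-nearest-neighbour mutual information, logistic
    regression AUC with stratified bootstrap confidence intervals), and an
    axisymmetric explicit finite-difference bioheat solver with focused/unfocused
    axial beam models, CEM43 thermal dosimetry and safety reporting, including an
    independent fine-grid reference solver for cross-validation of thermal output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    png,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    tiff,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
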