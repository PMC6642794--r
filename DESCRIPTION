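Package: viscomplexity
Title: Visual Complexity Modelling by Multiple Kernel Learning over Image
    Complexity Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models human ratings of visual complexity from image-derived
    complexity features. Computes compression-error (JPEG and quadtree
    fractal), edge-density and Zipf's-law metrics over HSV colour channels
    with optional Canny/Sobel edge-filter preprocessing; fits a
    feature-selection multiple kernel learning (FSMKL) regressor that fuses
    Gaussian and polynomial kernels built over filter-ranked nested subsets
    of correlated feature groups via a SimpleMKL-style projected gradient
    around epsilon-insensitive support vector regression; provides the
    standard comparison regressors (linear model, stepwise-AIC GLM, lasso,
    elastic net, kernel SVM-RFE), a repeated cross-validation benchmark
    harness with non-parametric model-comparison statistics, regression
    outlier diagnostics (leverage, studentized residuals, Cook's distance,
    Bonferroni outlier test, Tukey non-additivity), and seeded synthetic
    image and feature-table generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    kernlab,
    glmnet,
    jpeg,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
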