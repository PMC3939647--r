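Package: apspls
Title: All-Possible Sparse Partial Least Squares for Variable Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sparse partial least squares (SPLS) regression for a continuous
    outcome, fitted exhaustively over a grid of tuning parameters rather than
    at a single cross-validated optimum. For each predictor the package
    reports the percentage of grid cells in which it receives a non-zero
    standardized coefficient and the average of those non-zero estimates,
    giving a relative ranking of predictors that is robust to the instability
    of k-fold tuning under multicollinearity. Includes the traditional
    cross-validated tuner with a seed-sensitivity diagnostic, a block-collinear
    Monte-Carlo simulation study, and data-preparation utilities (skew
    transforms, externally studentized residual screening, and the Belsley
    condition-number diagnostic).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    jsonlite
Config/testthat/edition: 3
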