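Package: pearlitr
Title: Penalized EARL for High-Dimensional Individualized Treatment Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation and inference for linear individualized treatment
    rules from observational data with high-dimensional covariates.
    Implements penalized efficient augmentation and relaxation learning:
    a doubly robust, augmented inverse-probability weighted surrogate-loss
    estimator of the optimal linear rule with an l1 penalty and cross-fitted
    nuisance estimation (penalized regression, or distance-correlation
    screening followed by kernel smoothing).  Provides a split-and-pooled
    de-correlated score test and pooled one-step confidence intervals for
    individual rule coefficients, single-split normal inference for the
    value of an estimated rule, and a simulator for benchmark scenarios
    with known optimal rules.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    graphics,
    Rcpp,
    stats,
    tools,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
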