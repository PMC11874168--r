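Package: funqee
Title: Functional and Quantile Mixed-Effects Models for School-Day Energy
    Expenditure
Version: 0.1.0
Authors@R:
    person("funqee", "maintainers", email = "funqee@example.org",
           role = c("aut", "cre"))
Description: Scalar-on-function regression tools for studies that relate
    wearable-device energy-expenditure curves to body-weight outcomes in
    cluster-randomized school trials. Provides four model families sharing a
    school-level random intercept: a Gaussian linear mixed model (LMEM) and a
    quantile mixed model (QMEM) using the overall mean energy expenditure, and
    their functional counterparts (FMEM, FQMEM) in which the hourly
    energy-expenditure curve enters through integrated B-spline scores.
    Includes the asymmetric-Laplace marginal likelihood machinery for quantile
    mixed models, AIC selection of the spline basis dimension, bootstrap
    pointwise confidence bands for functional coefficients, a calibrated
    synthetic-data generator with known ground truth, and a command-line
    driver that produces machine-readable report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    splines,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
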