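Package: siecv
Title: Stepwise Internal-External Cross-Validation for Clinical
    Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Develops and validates clinical prediction models on
    clustered individual-participant data (multiple studies, centers or
    registries) with internal-external cross-validation: each cluster is
    iteratively held out, per-cluster Firth-penalized logistic models are
    pooled by univariate random-effects meta-analysis, and hold-out
    calibration, discrimination and Brier-score performance is
    meta-analyzed with Hartung-Knapp confidence intervals and approximate
    prediction intervals. A stepwise predictor-selection engine adds (or
    removes) candidate terms to optimize a configurable trade-off between
    average out-of-cluster performance and its between-cluster
    heterogeneity, and builds a final global model with shrinkage by the
    summary calibration slope and calibration-in-the-large. Includes a
    synthetic-data generator for clustered binary outcomes with
    controllable between-cluster heterogeneity.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
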