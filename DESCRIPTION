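Package: crlearn
Title: Residual and Inverse-Learning Estimation of Cognitive Resilience
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for operationalizing cognitive resilience (and other latent
    constructs defined as a deviation from an expected outcome) from tabular
    cohort data. Implements the standard residual approach (ordinary
    least-squares residuals as resilience estimates) and an inverse-learning
    approach in which an expectation model is trained only on samples defined
    to be non-resilient, applied to the remaining samples, and its
    cross-validated prediction error removed by a second error-correction
    model. Ships a ground-truth simulation suite with controllable predictor
    blocks, correlation, resilience prevalence and non-linear outcome
    transforms, plus experiment drivers that score estimators against the
    simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
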