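Package: conperform
Title: Continuous Functional Risk Scoring for Pulmonary Embolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derivation and evaluation of CON-PERFORM, a continuous prognostic
    score for 30-day mortality in acute pulmonary embolism built from three
    objective bedside parameters: age, heart rate, and arterial oxygen partial
    pressure (PaO2). Weighting coefficients are found by maximizing the ROC
    area under the curve over the normalized coefficient simplex, using
    Monte-Carlo sampling of reduced weight pairs and a bivariate polynomial
    response-surface surrogate. Includes the discrete PERFORM comparator
    score, ROC and Youden-threshold machinery with bootstrap confidence
    intervals, prognostic stratification into high- and low-risk groups with
    30-day outcome-state tabulation, a seeded synthetic-cohort generator with
    a known logistic outcome mechanism for end-to-end testing, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
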