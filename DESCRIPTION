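Package: diabrisk
Title: Model-Based Derivation and Evaluation of Diabetes Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derive and evaluate points-based diabetes risk scores from
    model-simulated populations. Provides an age-structured compartmental
    simulator of type 2 diabetes and its behavioural risk factors (obesity,
    smoking, physical inactivity) with light calibration to prevalence
    targets; Monte Carlo sampling of individual-level tables from the
    simulated population; derivation of integer points scores from
    multivariable logistic regression (points = round(10 * beta));
    diagnostic evaluation (ROC/AUC with bootstrap confidence intervals,
    Youden-style and constrained cut-offs, sensitivity, specificity,
    predictive values, proportion flagged for testing, per-stratum testing
    yields); and a synthetic-data generator with known ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
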