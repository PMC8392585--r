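Package: ntcpxero
Title: NTCP Modelling of Acute Salivary Dysfunction in Head and Neck Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to develop and validate normal tissue complication
    probability (NTCP) models for acute radiation-induced salivary
    dysfunction (xerostomia). Reduces parotid and oral-cavity dose-volume
    histograms to generalized equivalent uniform dose (gEUD) and point dose
    metrics, derives weekly CTCAE-based toxicity endpoints, screens dose
    metrics across the volume-effect grid, selects predictors by
    cross-validated LASSO, fits multivariable logistic NTCP models with
    bootstrap optimism correction, validates frozen models externally
    (discrimination, calibration-in-the-large, calibration slope,
    Hosmer-Lemeshow, predictive values), and renders nomograms and
    dose-response figures. Includes a fully synthetic cohort generator
    emulating published dosimetric, covariate and outcome structure so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
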