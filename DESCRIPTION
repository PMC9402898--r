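Package: pppscore
Title: MRI-Based Scoring and Diagnostic Evaluation for Pernicious Placenta Previa
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements an 11-item ordinal MRI scoring system for pernicious
    placenta previa (PPP) and the complete diagnostic-evaluation pipeline
    built on it: total-score computation with strict validation, ROC curves
    with Youden-index optimal cutoff selection for the three ordinal
    dichotomies of the placenta accreta spectrum (PAS), a full diagnostic
    metric suite (sensitivity, specificity, predictive values, likelihood
    ratios, Cohen's kappa), reconstruction of integer confusion tables from
    printed rates, a calibrated synthetic patient-cohort generator, and
    nonparametric and exact between-group comparisons of intraoperative
    blood loss and demographics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
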