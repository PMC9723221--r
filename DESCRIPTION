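Package: pedtriage
Title: Development and Evaluation of a Pediatric Emergency Triage Risk Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for developing, evaluating and deploying
    a logistic risk model that stratifies children presenting to an emergency
    department into non-urgent, priority and emergency triage categories.
    Includes a seeded synthetic-cohort generator with known effect sizes,
    composite outcome derivation (admission >= 24 h or readmission within
    48 h), median/mode imputation, the virtual-shunt transformation of
    pulse-oximetry oxygen saturation, events-per-variable screening,
    bootstrap-stepwise AIC consensus variable selection, cross-validated
    AUROC with bootstrap confidence intervals, bootstrap bias-corrected
    calibration, dual-threshold three-category risk stratification, and a
    published nine-predictor triage score as a fixed, exactly testable
    scoring function.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
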