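Package: ichmorph
Title: Hematoma Morphometry and Expansion-Prediction Modelling for
    Intracerebral Hemorrhage CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative three-dimensional morphometry of segmented
    intracerebral hematomas on non-contrast CT (voxel-counting volume,
    staircase-bias-corrected surface area, surface regularity index,
    density coefficient of variation), classification of hematoma
    expansion between baseline and follow-up scans, and construction and
    evaluation of nested logistic prediction models for expansion risk:
    LASSO-penalised variable selection with cross-validated tuning,
    nomogram point tables, AUROC with the DeLong test, continuous net
    reclassification improvement, integrated discrimination improvement,
    calibration curves and decision-curve analysis with bootstrap
    confidence intervals. Includes seed-deterministic generators for
    hematoma-like 3D phantoms with analytic reference geometry and for
    synthetic patient cohorts, so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    glmnet,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
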