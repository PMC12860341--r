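Package: mstriage
Title: Multistage Machine Learning for Clinical Referral Triage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Iterative multistage (stacked) classification for referral
    triage under heavy class imbalance. Each stage augments the feature
    matrix with the previous stages' out-of-fold predicted probabilities
    and refits an imbalance-aware base learner; the optimal number of
    stages is chosen by an elbow (maximal slope-change) criterion on the
    true-positive-rate trajectory. Includes a registry of ten baseline
    imbalance-aware classifiers with cross-validated evaluation, fold-based
    AUC confidence intervals, calibration binning, per-stage capture
    accounting, an argmax-with-review-margin triage decision rule, and a
    synthetic referral-cohort generator emulating a sparse-signal,
    heavily imbalanced multi-procedure cohort.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    rpart,
    randomForest,
    glmnet,
    e1071,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
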