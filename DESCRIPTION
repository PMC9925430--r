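Package: eegworkload
Title: EEG-Based Classification of Pilot Cognitive Workload
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for discriminating low, medium and high
    cognitive workload from multichannel scalp EEG recorded during flight
    maneuvers. Covers synthetic EEG generation with class-dependent band
    structure, preprocessing (zero-phase bandpass filtering, bad-channel
    detection, spherical-spline interpolation, amplitude-based artifact
    rejection), extraction of a 228-dimensional feature vector per two-minute
    segment (Welch band powers, theta/alpha, theta/beta and engagement
    ratios, log energy entropy), feature selection by SVM recursive feature
    elimination and cross-validated lasso, and a two-level stacking ensemble
    (SVM, random forest, logistic regression with a random-forest
    meta-learner) evaluated by stratified 10-fold cross-validation with
    macro-averaged metrics and ROC-AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    randomForest,
    nnet,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
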