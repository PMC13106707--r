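Package: fitrx
Title: Hybrid Sequence-Model BMI Classification and Personalized Exercise Prescription
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for classifying body-mass-index (BMI) categories from
    multivariate fitness-test sequences and turning the fitted model into
    personalized, adaptively adjusted exercise prescriptions. Implements a
    1D-convolutional + multi-head attention feature extractor trained with a
    weighted per-metric loss and an attention-entropy regularizer, leakage-safe
    SMOTE class rebalancing with Gaussian-noise augmentation inside stratified
    cross-validation folds, a regularized gradient-boosted classification stage,
    exact Shapley attribution over the four fitness metrics with rule-based
    prescription mapping and acute:chronic load monitoring, and the
    randomized-trial analysis stack (baseline-adjusted ANCOVA, Cohen's d on
    change scores, McNemar's test, category transition rates). A synthetic
    cohort and trial generator reproduces the statistical structure the
    framework assumes so the whole pipeline is testable without private data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xgboost,
    nnet,
    pROC
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
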