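Package: feigndep
Title: Mouse-Tracking Kinematics and Symptom Endorsement Analysis for
    Detecting Feigned Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the detection of malingered (feigned)
    depression from computer-mouse dynamics. Implements the full analysis
    pipeline for a double-choice questionnaire task: a nine-category
    stimulus protocol with conjunctive answer semantics, a seeded synthetic
    cohort generator that emits raw mouse trajectories and symptom
    endorsements calibrated to published group statistics, trajectory
    standardization with 101-frame time normalization, per-trial kinematic
    metrics (initiation and reaction time, maximum deviation and its
    latency, area under the curve, direction flips, velocity and
    acceleration), aggregation into an 83-feature participant vector,
    one-way ANOVA with omega-squared effect sizes and Tukey post hoc tests,
    correlation-based feature selection with greedy stepwise search, and
    classification (native Gaussian naive Bayes, an interpretable two-rule
    decision tree, a depth-2 CART-style tree, and adapters to standard
    classifiers) evaluated by stratified k-fold cross-validation and
    held-out cohorts.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    e1071,
    nnet,
    randomForest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
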