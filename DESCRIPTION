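Package: gapdml
Title: Explainable Double Machine Learning for the Physical Activity
    Intention-Behavior Gap
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the physical-activity intention-behavior gap
    with an explainable double-machine-learning workflow. Provides a
    factor-model simulator for 7-point Likert survey data with PARS-3
    activity triples and ordinal demographics; psychometric validation
    statistics (Cronbach's alpha, average variance extracted, composite
    reliability, KMO, Bartlett's sphericity); the baseline-corrected
    standardized gap outcome; a five-algorithm predictive benchmarking
    harness with cross-validated grid search; exact and permutation-sampled
    Shapley attribution with LOWESS dependence curves; and a cross-fitted
    partial-linear double-machine-learning estimator of average treatment
    effects with bootstrap inference and median-split subgroup analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    xgboost,
    ranger,
    e1071,
    rpart
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
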