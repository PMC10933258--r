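Package: gaitpath
Title: Foot-Condition Classification from Gait-Cycle Kinematics with
    Interpretable Ensemble Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for classifying foot conditions from
    stride-averaged functional-angle time series. From 101-point gait-cycle
    profiles of twelve foot and ankle angles it derives first-gradient and
    difference-from-normative series, computes a canonical set of 374
    phase-wise scalar features, selects features by intersecting recursive
    feature elimination (linear support vector machine estimator) with
    random-forest importance thresholding, trains a weighted soft-voting
    ensemble of four probabilistic classifiers, and attributes each
    prediction to its most influential kinematic features through local
    surrogate (LIME) explanations aggregated per condition. Includes a
    seed-reproducible synthetic cohort generator with plantable,
    recoverable per-condition kinematic effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    ranger,
    glmnet,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
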