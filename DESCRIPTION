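Package: msprogrisk
Title: Risk Stratification and Dynamic Prediction of Disease Progression
    in Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating 5-year risk of disease progression in
    relapsing-remitting multiple sclerosis from longitudinal clinical
    registry data. Implements a transparent 0-12 point risk score (DAAE-M)
    with disease-modifying-therapy (DMT) conditional risk reference tables
    and propensity-score-matched treatment comparisons, and a dynamic
    landmark-based individualized risk model (ELIE) fitted with
    class-weighted L1-penalized logistic regression. Includes an objective
    confirmed-disability-progression detector (EDSS with functional-system
    confirmation, relapse-free), longitudinal DMT-exposure classifiers,
    calibration and discrimination validation metrics, and a synthetic
    registry generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    mgcv,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
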