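Package: motorfair
Title: Fairness Auditing of Remote Motor-Assessment Classifiers on Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates demographically structured cohorts performing a
    web-based motor and working-memory assessment battery (mouse tracing,
    timed key presses, target clicking, digit span), extracts a 79-feature
    digital-phenotyping matrix, trains classical classifiers for
    Parkinson's disease status, and audits their predictions for group
    fairness (disparate impact, equal opportunity, equalized odds) across
    sex, race, device type and handedness with group-balanced bootstrap
    resampling, SMOTE class rebalancing, subgroup resampling, stratified
    feature importance, and a closed-form AUROC sample-size calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    randomForest,
    xgboost,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
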