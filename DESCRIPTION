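Package: fairselect
Title: Fairness-Aware Assessment, Selection, and Explanation of Clinical Risk Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage workflow for responsible development of binary clinical
    risk classifiers on tabular cohorts. Stage one assesses candidate models by
    discrimination (AUC), threshold-optimized sensitivity, specificity and accuracy,
    and by the Relative Parity of Performance Score (RPPS), a fairness metric based
    on subgroup-conditional AUCs over protected attributes. Stage two sweeps an
    accuracy-fairness trade-off weight to map which model dominates at each
    preference. Stage three explains the chosen model with bootstrapped permutation
    importance, (relative) Shapley values on the log-odds scale, and partial
    dependence curves in both risk and log-odds. A synthetic cohort generator with
    known logistic ground truth makes every stage testable without restricted
    clinical data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    glmnet,
    rpart,
    randomForest,
    xgboost,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
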