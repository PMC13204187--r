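Package: pmfscreen
Title: Positive-Unlabeled Screening for Primary Myelofibrosis in Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening large electronic-health-record (EHR)
    populations for primary myelofibrosis (PMF), a rare myeloproliferative
    neoplasm, when only a small set of confirmed cases is labeled and the
    remaining records are an unlabeled mixture of cases and non-cases.
    Implements a synthetic positive-unlabeled longitudinal cohort generator
    calibrated to published complete-blood-count (CBC) distributions,
    two-year analysis-window extraction with stratified control matching,
    longitudinal feature aggregation with control-anchored decile binning,
    class-balanced univariate logistic screening with false-discovery-rate
    control, Elkan-Noto probability calibration and spy-based
    reliable-negative mining over pluggable base learners, and a repeated
    stratified cross-validation evaluation framework built around
    non-interpolated average precision, recall-binned precision-recall
    profiles, consensus misclassification analysis, and screening-workload
    arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    glmnet,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
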