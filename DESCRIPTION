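Package: xmittn
Title: Cross-Validated Null-Hypothesis Testing and Bootstrap Validation of
    Biomarker-Classifier Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Four-stage validation of biomarker-classifier combinations
    across two independent cohorts: repeated stratified train/CV splitting
    of a training cohort, dual feature-set fitting of nine classification
    algorithms, empirical Gini-index null-hypothesis p-values with
    unadjusted model selection, and frozen-model bootstrap validation on an
    independent test cohort with per-subject dementia-probability P(AD)
    staging and longitudinal cognitive-slope comparison. Includes cohort
    harmonization (reference-population z-scoring of log CSF complement C3),
    Table-1-style cohort summaries, and a seeded synthetic-cohort generator
    so the entire pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    jsonlite,
    ranger,
    Rcpp,
    rpart,
    xgboost
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
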