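Package: keydyn
Title: Keystroke Dynamics Pipelines for Remote Disability Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to turn raw smartphone keystroke press/release event streams
    into timing sequences (hold time, flight time, press-press and
    release-release latency, plus punctuation- and correction-conditioned
    flight times), aggregate them into daily summary features and composite
    fine-motor and cognition scores, and train subject-level three-stage
    binary classifiers (normalisation with chained-equation imputation, a
    soft-voting probability ensemble over days, and per-subject probability
    averaging) for clinical diagnosis and binarized disability outcomes in
    multiple sclerosis cohorts. Includes a seedable synthetic keystroke-cohort
    generator, leave-one-subject-out and grouped cross-validation utilities,
    recursive feature elimination with cross-classifier consensus, bootstrap
    AUC confidence intervals, exact contingency-table tests, and exact Shapley
    value attribution by subset enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    MASS,
    class,
    e1071,
    ranger,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
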