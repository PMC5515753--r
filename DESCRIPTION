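Package: mcirisk
Title: Risk Scores and Evaluation Statistics for Malignant Cerebral
    Infarction Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing and evaluating bedside risk scores for
    large hemispheric infarction (LHI) cohorts: middle-cerebral-artery
    infarct classification (complete vs incomplete), the CHADS2 score, a
    five-component CMCA score, and two in-hospital mortality scores, with
    published cutoffs. Includes from-scratch evaluation statistics
    (empirical ROC curves and AUC, Youden-index cutoff selection,
    sensitivity/specificity, uncorrected Pearson chi-square and Fisher
    exact tests for 2x2 tables, two-sample t tests), a calibrated synthetic
    cohort generator for end-to-end testing, and a pipeline that reads a
    per-patient cohort table, scores every patient, produces group
    comparisons and ROC analyses, and writes a structured report.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
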