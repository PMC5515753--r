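#' Read and write cohort tables
#'
#' Cohort files are comma-separated UTF-8 text with a header row and the
#' columns of [cohort_columns()]. Binary fields are encoded 0/1; an
#' absent day-5 NIHSS is an empty field; `territories` is a
#' semicolon-joined subset of `deep;superior;posterior`.
#'
#' `read_cohort()` validates every row: a missing required column is an
#' error naming the column; rows violating a record invariant are dropped
#' with a warning and reported, with row numbers and fields, in the
#' `problems` attribute (see [cohort_problems()]).
#'
#' @param path File path.
#' @return `read_cohort()`: a validated cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      sex = readr::col_character(),
      territories = readr::col_character(),
      mca_fraction = readr::col_double(),
      .default = readr::col_integer()
    )
  )
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  logicals <- setdiff(cohort_columns(),
                      c("patient_id", "age", "sex", "nihss_admission",
                        "nihss_day5", "territories", "mca_fraction"))
  raw <- dplyr::mutate(raw, dplyr::across(dplyr::all_of(logicals), ~ .x == 1L),
                       territories = dplyr::coalesce(.data$territories, ""))
  validate_cohort(raw, action = "drop")
}

#' @rdname read_cohort
#' @param data A cohort data frame.
#' @return `write_cohort()`: `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  data <- validate_cohort(data, action = "error")
  logicals <- names(data)[vapply(data, is.logical, logical(1))]
  out <- dplyr::mutate(data,
                       dplyr::across(dplyr::all_of(logicals), as.integer))
  readr::write_csv(out[, cohort_columns()], path, na = "")
  invisible(path)
}

#' Group comparison table (CMCA vs IMCA)
#'
#' Compares every numeric variable by a two-sample t test and every
#' binary variable by a 2x2 Pearson chi-square test between the complete
#' and incomplete MCA infarction groups, in the style of a clinical
#' Table 1. Percentages use half-up rounding to one decimal. When a
#' binary variable has a zero margin (e.g. no events at all) the test is
#' skipped and the p-value reported as `NA`.
#'
#' @inheritParams classify_infarct
#' @param correct Use the Yates continuity correction in the chi-square
#'   tests? Default `FALSE`.
#' @param var_equal Pool the t-test variances (Student)? Default `TRUE`.
#' @return A tibble: `variable`, `type`, per-group summary columns
#'   (`cmca`, `imca` formatted strings, plus raw `cmca_value`,
#'   `imca_value`), `statistic`, `p_value`.
#' @export
compare_groups <- function(data, cutoffs = score_cutoffs(), correct = FALSE,
                           var_equal = TRUE) {
  data <- classify_infarct(data, cutoffs)
  data <- dplyr::filter(data, .data$infarct_class != "NOT_LHI")
  g1 <- data[data$infarct_class == "CMCA", ]
  g2 <- data[data$infarct_class == "IMCA", ]
  if (nrow(g1) < 2 || nrow(g2) < 2) {
    abort("need at least 2 patients in each infarct group for comparisons")
  }
  numeric_vars <- c("age", "nihss_admission", "nihss_day5", "mca_fraction")
  binary_vars <- c("male_sex", cohort_binary_fields(),
                   "hypodensity_gt_one_third", "hmcas", "brain_edema",
                   "stroke_in_progression", "died_in_hospital", "thrombolysis",
                   "craniectomy")
  data$male_sex <- data$sex == "male"
  suppressWarnings(data$stroke_in_progression <- stroke_in_progression(data))
  g1 <- data[data$infarct_class == "CMCA", ]
  g2 <- data[data$infarct_class == "IMCA", ]

  num_rows <- purrr::map(numeric_vars, function(v) {
    x <- g1[[v]]; y <- g2[[v]]
    tt <- t_test2(x, y, var_equal = var_equal)
    tibble(variable = v, type = "numeric",
           cmca = sprintf("%.1f ± %.1f", mean(x, na.rm = TRUE), sd(x, na.rm = TRUE)),
           imca = sprintf("%.1f ± %.1f", mean(y, na.rm = TRUE), sd(y, na.rm = TRUE)),
           cmca_value = mean(x, na.rm = TRUE), imca_value = mean(y, na.rm = TRUE),
           statistic = tt$statistic, p_value = tt$p_value)
  })
  bin_rows <- purrr::map(binary_vars, function(v) {
    k1 <- sum(g1[[v]]); k2 <- sum(g2[[v]])
    tab <- table2x2(k1, nrow(g1) - k1, k2, nrow(g2) - k2)
    test <- tryCatch(chi2_test_2x2(tab, correct = correct),
                     error = function(e) tibble(statistic = NA_real_,
                                                df = NA_integer_,
                                                p_value = NA_real_))
    tibble(variable = v, type = "binary",
           cmca = sprintf("%d/%d (%.1f%%)", k1, nrow(g1), pct(k1, nrow(g1))),
           imca = sprintf("%d/%d (%.1f%%)", k2, nrow(g2), pct(k2, nrow(g2))),
           cmca_value = k1 / nrow(g1), imca_value = k2 / nrow(g2),
           statistic = test$statistic, p_value = test$p_value)
  })
  dplyr::bind_rows(num_rows, bin_rows)
}

#' Journal-style p-value string
#'
#' Formats a raw p-value the way clinical journals print them
#' (`P < .001`, otherwise two or three decimals with no leading zero).
#' The raw value is always reported alongside this string in package
#' output; the string is cosmetic only.
#'
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  out <- ifelse(p < 0.001, "< .001",
                ifelse(p < 0.045, sub("^0", "", sprintf("= %.3f", p)),
                       sub("^0", "", sprintf("= %.2f", p))))
  ifelse(is.na(p), "NA", paste0("P ", out))
}

#' Full cohort analysis
#'
#' End-to-end analysis of an LHI cohort: scores every patient
#' ([score_patients()]), builds the CMCA-vs-IMCA group-comparison table
#' ([compare_groups()]), and runs the three ROC analyses — the CMCA score
#' against CMCA group membership, and the two mortality scores against
#' in-hospital death — reporting for each the AUC, the Youden-optimal
#' cutoff, and sensitivity/specificity at both the optimal and the
#' published default cutoff. ROC sections that cannot be computed (an
#' outcome with a single class) are omitted with an explicit notice.
#'
#' @inheritParams compare_groups
#' @return An object of class `cohort_analysis` with elements `summary`,
#'   `comparison`, `scores`, `rocs`, `roc_notes`, `provenance`. Methods:
#'   [tidy()] (per-score ROC summary), [glance()] (one-row cohort
#'   summary), [autoplot()], [print()], [write_report()].
#' @examples
#' fit <- simulate_cohort(seed = 7) |> analyze_cohort()
#' glance(fit)
#' tidy(fit)
#' @export
analyze_cohort <- function(data, cutoffs = score_cutoffs(), correct = FALSE,
                           var_equal = TRUE) {
  data <- validate_cohort(data, action = "error")
  scores <- suppressWarnings(score_patients(data, cutoffs))
  full <- dplyr::left_join(data, scores, by = "patient_id")
  lhi <- dplyr::filter(full, .data$infarct_class != "NOT_LHI")

  n <- nrow(data)
  deaths <- sum(data$died_in_hospital)
  summary <- tibble(
    n = n,
    n_cmca = sum(scores$infarct_class == "CMCA"),
    n_imca = sum(scores$infarct_class == "IMCA"),
    n_not_lhi = sum(scores$infarct_class == "NOT_LHI"),
    deaths = deaths,
    mortality_pct = pct(deaths, n),
    stroke_in_progression = sum(scores$stroke_in_progression),
    stroke_in_progression_pct = pct(sum(scores$stroke_in_progression), n)
  )

  comparison <- compare_groups(data, cutoffs, correct = correct,
                               var_equal = var_equal)

  roc_spec <- list(
    cmca_score = list(score = "cmca_score", outcome = "cmca_membership",
                      default = cutoffs$cmca),
    mortality1 = list(score = "mortality1", outcome = "died_in_hospital",
                      default = cutoffs$mortality1),
    mortality2 = list(score = "mortality2", outcome = "died_in_hospital",
                      default = cutoffs$mortality2)
  )
  rocs <- list()
  roc_notes <- character()
  for (nm in names(roc_spec)) {
    sp <- roc_spec[[nm]]
    d <- lhi
    d$.outcome <- if (sp$outcome == "cmca_membership") {
      d$infarct_class == "CMCA"
    } else {
      d$died_in_hospital
    }
    d <- d[!is.na(d[[sp$score]]), ]
    if (nrow(d) < 2 || length(unique(d$.outcome)) < 2) {
      roc_notes[nm] <- paste0("ROC for ", nm, " omitted: outcome '",
                              sp$outcome, "' has a single class")
      next
    }
    roc <- roc_curve(d, .data[[sp$score]], .data$.outcome)
    at_default <- sens_spec(d, .data[[sp$score]], .data$.outcome, sp$default)
    rocs[[nm]] <- list(score = sp$score, outcome = sp$outcome, roc = roc,
                       default_cutoff = sp$default, at_default = at_default)
  }

  provenance <- list(
    package = "mcirisk",
    version = as.character(packageVersion("mcirisk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    cutoffs = unclass(cutoffs),
    options = list(correct = correct, var_equal = var_equal),
    config_hash = rlang::hash(list(unclass(cutoffs), correct, var_equal))
  )

  structure(
    list(summary = summary, comparison = comparison, scores = scores,
         rocs = rocs, roc_notes = roc_notes, provenance = provenance),
    class = "cohort_analysis"
  )
}

#' @export
glance.cohort_analysis <- function(x, ...) {
  aucs <- purrr::map_dbl(x$rocs, ~ .x$roc$auc)
  dplyr::bind_cols(x$summary,
                   tibble(!!!stats::setNames(as.list(aucs),
                                             paste0("auc_", names(aucs)))))
}

#' @export
tidy.cohort_analysis <- function(x, ...) {
  purrr::imap(x$rocs, function(r, nm) {
    tibble(
      score = nm, outcome = r$outcome, auc = r$roc$auc,
      best_cutoff = r$roc$best_cutoff,
      sens_at_best = r$roc$sens_at_best, spec_at_best = r$roc$spec_at_best,
      default_cutoff = r$default_cutoff,
      sens_at_default = r$at_default$sensitivity,
      spec_at_default = r$at_default$specificity
    )
  }) |> dplyr::bind_rows()
}

#' @export
print.cohort_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("LHI cohort analysis: n = %d (CMCA %d, IMCA %d%s)\n",
              s$n, s$n_cmca, s$n_imca,
              if (s$n_not_lhi > 0) sprintf(", below LHI %d", s$n_not_lhi) else ""))
  cat(sprintf("  in-hospital deaths %d (%.1f%%); stroke in progression %d (%.1f%%)\n",
              s$deaths, s$mortality_pct, s$stroke_in_progression,
              s$stroke_in_progression_pct))
  td <- tidy(x)
  if (nrow(td) > 0) {
    cat("  ROC analyses:\n")
    for (i in seq_len(nrow(td))) {
      cat(sprintf("    %-11s vs %-16s AUC %.2f; cutoff %g (sens %.1f%%, spec %.1f%%)\n",
                  td$score[i], td$outcome[i], td$auc[i], td$best_cutoff[i],
                  100 * td$sens_at_best[i], 100 * td$spec_at_best[i]))
    }
  }
  for (note in x$roc_notes) cat("  note:", note, "\n")
  invisible(x)
}

#' Serialize and restore an analysis report
#'
#' `write_report()` writes a `cohort_analysis` as structured JSON at full
#' numeric precision (plus provenance: package version, config hash,
#' cutoffs, timestamp); `read_report()` restores it as a plain nested
#' list whose numbers round-trip losslessly.
#'
#' @param x A `cohort_analysis` object.
#' @param path Output file path (`.json`).
#' @return `write_report()`: `path` invisibly. `read_report()`: a nested
#'   list.
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "cohort_analysis"))
  jsonlite::write_json(report_as_list(x), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

report_as_list <- function(x) {
  td <- tidy(x)
  list(
    summary = as.list(x$summary),
    comparison = dplyr::mutate(x$comparison,
                               p_string = format_p(.data$p_value)),
    roc_summary = td,
    roc_points = purrr::map(x$rocs, ~ .x$roc$points),
    roc_notes = as.list(x$roc_notes),
    scores = dplyr::mutate(x$scores,
                           infarct_class = as.character(.data$infarct_class)),
    provenance = x$provenance
  )
}
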