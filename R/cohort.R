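#' Cohort table schema
#'
#' A cohort is a data frame with one row per patient. `cohort_columns()`
#' returns the required column names in canonical order; `empty_cohort()`
#' returns a zero-row tibble with the right types, useful as a template.
#'
#' Binary clinical fields are logical in R and encoded 0/1 on disk.
#' `territories` is a semicolon-joined subset of `deep;superior;posterior`.
#' `nihss_day5` may be `NA` (not assessed); every other field is required.
#'
#' @return `cohort_columns()`: a character vector. `empty_cohort()`: a
#'   zero-row tibble.
#' @export
cohort_columns <- function() {
  c("patient_id", "age", "sex",
    cohort_binary_fields(),
    "nihss_admission", "nihss_day5",
    "hypodensity_gt_one_third", "hmcas", "brain_edema",
    "territories", "mca_fraction",
    "died_in_hospital", "stroke_related_death", "thrombolysis", "craniectomy")
}

#' @rdname cohort_columns
#' @export
empty_cohort <- function() {
  tibble(
    patient_id = character(), age = integer(), sex = character(),
    chf = logical(), hypertension = logical(), diabetes = logical(),
    prior_stroke_or_tia = logical(), atrial_fibrillation = logical(),
    smoking = logical(), hypercholesterolemia = logical(),
    coronary_artery_disease = logical(),
    nihss_admission = integer(), nihss_day5 = integer(),
    hypodensity_gt_one_third = logical(), hmcas = logical(),
    brain_edema = logical(),
    territories = character(), mca_fraction = double(),
    died_in_hospital = logical(), stroke_related_death = logical(),
    thrombolysis = logical(), craniectomy = logical()
  )
}

cohort_binary_fields <- function() {
  c("chf", "hypertension", "diabetes", "prior_stroke_or_tia",
    "atrial_fibrillation", "smoking", "hypercholesterolemia",
    "coronary_artery_disease")
}

mca_territories <- function() c("deep", "superior", "posterior")

parse_territories <- function(x) {
  out <- strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE)
  lapply(out, function(t) t[t != ""])
}

#' Validate a cohort table
#'
#' Checks every patient row against the record invariants: age in
#' \[18, 120\], NIHSS scores in \[0, 42\], `mca_fraction` in \[0, 1\],
#' territories a subset of `deep;superior;posterior`, stroke-related death
#' implying in-hospital death, and well-formed sex and binary fields.
#' A missing required column is always an error naming the column.
#'
#' @param data A cohort data frame (see [cohort_columns()]).
#' @param action What to do with invalid rows: `"error"` (default) aborts
#'   listing row and field, `"drop"` removes offending rows with a warning,
#'   `"keep"` only records the problems.
#' @return The (possibly filtered) cohort as a tibble, invisibly carrying a
#'   `problems` attribute: a tibble with columns `row`, `field`, `message`
#'   (zero rows when the cohort is clean). Retrieve it with
#'   [cohort_problems()].
#' @export
validate_cohort <- function(data, action = c("error", "drop", "keep")) {
  action <- match.arg(action)
  missing_cols <- setdiff(cohort_columns(), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- as_tibble(data)
  probs <- list()
  note <- function(rows, field, msg) {
    if (length(rows) > 0) {
      probs[[length(probs) + 1L]] <<- tibble(row = rows, field = field, message = msg)
    }
  }

  bad <- which(!(data$age >= 18 & data$age <= 120) | is.na(data$age))
  note(bad, "age", "age must be an integer in [18, 120]")
  bad <- which(!(data$sex %in% c("male", "female")) | is.na(data$sex))
  note(bad, "sex", "sex must be 'male' or 'female'")
  bad <- which(!(data$nihss_admission >= 0 & data$nihss_admission <= 42) |
                 is.na(data$nihss_admission))
  note(bad, "nihss_admission", "NIHSS at admission must be in [0, 42]")
  bad <- which(!is.na(data$nihss_day5) &
                 !(data$nihss_day5 >= 0 & data$nihss_day5 <= 42))
  note(bad, "nihss_day5", "NIHSS at day 5 must be in [0, 42] or absent")
  bad <- which(!(data$mca_fraction >= 0 & data$mca_fraction <= 1) |
                 is.na(data$mca_fraction))
  note(bad, "mca_fraction", "mca_fraction must be in [0, 1]")

  terr <- parse_territories(data$territories)
  bad <- which(vapply(terr, function(t) {
    any(!t %in% mca_territories()) || anyDuplicated(t) > 0
  }, logical(1)))
  note(bad, "territories",
       "territories must be a ;-joined subset of deep;superior;posterior")

  for (f in c(cohort_binary_fields(), "hypodensity_gt_one_third", "hmcas",
              "brain_edema", "died_in_hospital", "stroke_related_death",
              "thrombolysis", "craniectomy")) {
    bad <- which(is.na(data[[f]]))
    note(bad, f, paste0(f, " must be 0/1 (logical), not missing"))
  }
  bad <- which(!is.na(data$stroke_related_death) & !is.na(data$died_in_hospital) &
                 data$stroke_related_death & !data$died_in_hospital)
  note(bad, "stroke_related_death",
       "stroke_related_death requires died_in_hospital")

  problems <- if (length(probs) == 0) {
    tibble(row = integer(), field = character(), message = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(probs), .data$row, .data$field)
  }

  if (nrow(problems) > 0 && action == "error") {
    hdr <- paste0("invalid cohort rows (", length(unique(problems$row)), "):")
    lines <- paste0("row ", problems$row, ", ", problems$field, ": ",
                    problems$message)
    abort(paste(c(hdr, utils::head(lines, 10)), collapse = "\n"))
  }
  if (nrow(problems) > 0 && action == "drop") {
    warn(paste0("dropping ", length(unique(problems$row)),
                " invalid row(s); see cohort_problems()"))
    keep <- setdiff(seq_len(nrow(data)), unique(problems$row))
    data <- data[keep, , drop = FALSE]
  }
  attr(data, "problems") <- problems
  invisible(data)
}

#' @rdname validate_cohort
#' @export
cohort_problems <- function(data) {
  attr(data, "problems") %||%
    tibble(row = integer(), field = character(), message = character())
}
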