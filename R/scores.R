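#' Score cutoffs and thresholds
#'
#' All thresholds used by the scoring functions, with the published values
#' as defaults. Every threshold is inclusive (a value equal to the cutoff
#' meets the criterion).
#'
#' @param nihss_admission Admission NIHSS threshold for the CMCA-score
#'   severity component (default 17).
#' @param nihss_peak NIHSS threshold for the mortality-score-2 severity
#'   component (default 26), applied to the peak NIHSS in the first five
#'   days (see `nihss_window`).
#' @param chads2 CHADS2 threshold used as a component of both mortality
#'   scores (default 4).
#' @param cmca Positivity cutoff for the five-point CMCA score (default 2).
#' @param mortality1 Positivity cutoff for mortality score 1 (default 1).
#' @param mortality2 Positivity cutoff for mortality score 2 (default 2).
#' @param lhi_fraction MCA-territory fraction at or above which an infarct
#'   counts as a large hemispheric infarction (default 0.5).
#' @param nihss_window Which NIHSS the mortality-score-2 severity component
#'   uses: `"first5"` (default) takes the maximum of admission and day-5
#'   NIHSS, `"day5"` uses the day-5 value only (falling back to admission
#'   when day 5 is not assessed).
#' @return A list of class `score_cutoffs`.
#' @export
score_cutoffs <- function(nihss_admission = 17, nihss_peak = 26, chads2 = 4,
                          cmca = 2, mortality1 = 1, mortality2 = 2,
                          lhi_fraction = 0.5,
                          nihss_window = c("first5", "day5")) {
  nihss_window <- match.arg(nihss_window)
  stopifnot(nihss_admission >= 0, nihss_peak >= 0, chads2 >= 0,
            lhi_fraction >= 0, lhi_fraction <= 1)
  structure(
    list(nihss_admission = nihss_admission, nihss_peak = nihss_peak,
         chads2 = chads2, cmca = cmca, mortality1 = mortality1,
         mortality2 = mortality2, lhi_fraction = lhi_fraction,
         nihss_window = nihss_window),
    class = "score_cutoffs"
  )
}

#' Classify MCA infarcts as complete, incomplete, or below LHI size
#'
#' Complete MCA infarction (CMCA) means all three MCA territories (deep,
#' superior, posterior) are involved, regardless of the estimated territory
#' fraction. Otherwise the infarct is incomplete (IMCA) when it covers at
#' least half of the MCA territory, and below the large-hemispheric-
#' infarction threshold (`NOT_LHI`) when it does not.
#'
#' @param data A cohort data frame with `territories` and `mca_fraction`
#'   columns.
#' @param cutoffs A [score_cutoffs()] object (supplies the LHI fraction
#'   threshold).
#' @return `data` as a tibble with an added `infarct_class` factor column
#'   with levels `CMCA`, `IMCA`, `NOT_LHI`.
#' @examples
#' classify_infarct(tibble::tibble(
#'   territories = c("deep;superior;posterior", "deep;superior", "deep"),
#'   mca_fraction = c(1.0, 0.6, 0.3)
#' ))
#' @export
classify_infarct <- function(data, cutoffs = score_cutoffs()) {
  terr <- parse_territories(data$territories)
  bad <- unlist(lapply(terr, setdiff, y = mca_territories()))
  if (length(bad) > 0) {
    abort(paste0("invalid territory name(s): ", paste(unique(bad), collapse = ", ")))
  }
  if (any(is.na(data$mca_fraction) | data$mca_fraction < 0 | data$mca_fraction > 1)) {
    abort("mca_fraction must be in [0, 1]")
  }
  complete <- vapply(terr, function(t) length(unique(t)) == 3L, logical(1))
  cls <- ifelse(complete, "CMCA",
                ifelse(data$mca_fraction >= cutoffs$lhi_fraction, "IMCA", "NOT_LHI"))
  dplyr::mutate(as_tibble(data),
                infarct_class = factor(cls, levels = c("CMCA", "IMCA", "NOT_LHI")))
}

chads2_components <- function(data, cutoffs = score_cutoffs()) {
  tibble(
    patient_id = rep(data$patient_id, each = 5L),
    score = "chads2",
    component = rep(c("chf", "hypertension", "age_ge_75", "diabetes",
                      "prior_stroke_or_tia"), times = nrow(data)),
    met = as.vector(rbind(data$chf, data$hypertension, data$age >= 75,
                          data$diabetes, data$prior_stroke_or_tia)),
    points = rep(c(1L, 1L, 1L, 1L, 2L), times = nrow(data))
  )
}

#' Stroke in progression within the first five days
#'
#' A patient is in progression when the NIHSS increased by two or more
#' points between admission and day 5, or when the death was stroke
#' related. A survivor with no day-5 assessment evaluates to `FALSE` and
#' triggers a single data-completeness warning for the cohort.
#'
#' @inheritParams classify_infarct
#' @return A logical vector, one element per row of `data`.
#' @export
stroke_in_progression <- function(data) {
  delta_met <- !is.na(data$nihss_day5) &
    (data$nihss_day5 - data$nihss_admission >= 2)
  incomplete <- is.na(data$nihss_day5) & !data$stroke_related_death &
    !data$died_in_hospital
  if (any(incomplete)) {
    warn(paste0(sum(incomplete), " survivor(s) lack a day-5 NIHSS; ",
                "stroke in progression set to FALSE for them"))
  }
  delta_met | data$stroke_related_death
}

peak_nihss <- function(data, window = "first5") {
  if (window == "first5") {
    pmax(data$nihss_admission, data$nihss_day5, na.rm = TRUE)
  } else {
    ifelse(is.na(data$nihss_day5), data$nihss_admission, data$nihss_day5)
  }
}

#' Per-patient risk-score table
#'
#' Computes, for every patient, the infarct class and all four scores:
#' CHADS2 (CHF, hypertension, age >= 75, diabetes 1 point each; prior
#' stroke/TIA 2 points; range 0-6), the five-component CMCA score
#' (>1/3 early hypodensity, hyperdense MCA sign, brain edema, admission
#' NIHSS >= 17, stroke in progression; 1 point each), mortality score 1
#' (CMCA infarct, CHADS2 >= 4; 1 point each) and mortality score 2 (CMCA
#' infarct, CHADS2 >= 4, peak NIHSS in the first five days >= 26; 1 point
#' each). Positivity flags use the cutoffs in `cutoffs`.
#'
#' The mortality scores are defined for large hemispheric infarctions
#' only: patients classified `NOT_LHI` get `NA` mortality scores (an
#' explicit not-applicable marker) rather than an error.
#'
#' @inheritParams classify_infarct
#' @return A tibble with one row per patient: `patient_id`,
#'   `infarct_class`, `chads2`, `stroke_in_progression`, `nihss_peak5`,
#'   `cmca_score`, `mortality1`, `mortality2`, and a `*_positive` logical
#'   for each scored cutoff.
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' score_patients(cohort)
#' @export
score_patients <- function(data, cutoffs = score_cutoffs()) {
  data <- classify_infarct(data, cutoffs)
  sip <- stroke_in_progression(data)
  chads2 <- data$chf + data$hypertension + (data$age >= 75) + data$diabetes +
    2L * data$prior_stroke_or_tia
  cmca_score <- data$hypodensity_gt_one_third + data$hmcas + data$brain_edema +
    (data$nihss_admission >= cutoffs$nihss_admission) + sip
  peak <- peak_nihss(data, cutoffs$nihss_window)
  is_cmca <- data$infarct_class == "CMCA"
  lhi <- data$infarct_class != "NOT_LHI"
  m1 <- ifelse(lhi, is_cmca + (chads2 >= cutoffs$chads2), NA_integer_)
  m2 <- ifelse(lhi, is_cmca + (chads2 >= cutoffs$chads2) +
                 (peak >= cutoffs$nihss_peak), NA_integer_)
  tibble(
    patient_id = data$patient_id,
    infarct_class = data$infarct_class,
    chads2 = as.integer(chads2),
    chads2_positive = chads2 >= cutoffs$chads2,
    stroke_in_progression = sip,
    nihss_peak5 = as.integer(peak),
    cmca_score = as.integer(cmca_score),
    cmca_positive = cmca_score >= cutoffs$cmca,
    mortality1 = as.integer(m1),
    mortality1_positive = m1 >= cutoffs$mortality1,
    mortality2 = as.integer(m2),
    mortality2_positive = m2 >= cutoffs$mortality2
  )
}

#' Per-component score breakdown
#'
#' Long-format view of one score: one row per patient and component, with
#' whether the component is met, its point value, and the per-patient
#' total, cutoff and positivity. The two mortality scores are defined for
#' large hemispheric infarctions only; a `NOT_LHI` patient in `data` is a
#' domain error for them.
#'
#' @inheritParams classify_infarct
#' @param score Which score to break down.
#' @return A tibble with columns `patient_id`, `score`, `component`, `met`,
#'   `points`, `total`, `cutoff`, `positive`.
#' @export
score_breakdown <- function(data,
                            score = c("chads2", "cmca", "mortality1", "mortality2"),
                            cutoffs = score_cutoffs()) {
  score <- match.arg(score)
  data <- classify_infarct(data, cutoffs)
  comp <- switch(score,
    chads2 = chads2_components(data, cutoffs),
    cmca = {
      sip <- stroke_in_progression(data)
      tibble(
        patient_id = rep(data$patient_id, each = 5L),
        score = "cmca",
        component = rep(c("hypodensity_gt_one_third", "hmcas", "brain_edema",
                          "nihss_admission_ge_cutoff", "stroke_in_progression"),
                        times = nrow(data)),
        met = as.vector(rbind(data$hypodensity_gt_one_third, data$hmcas,
                              data$brain_edema,
                              data$nihss_admission >= cutoffs$nihss_admission,
                              sip)),
        points = 1L
      )
    },
    mortality1 = ,
    mortality2 = {
      if (any(data$infarct_class == "NOT_LHI")) {
        abort("mortality scores are defined for LHI patients only (CMCA or IMCA); filter NOT_LHI rows first")
      }
      chads2 <- data$chf + data$hypertension + (data$age >= 75) + data$diabetes +
        2L * data$prior_stroke_or_tia
      base <- list(
        component = c("cmca_infarct", "chads2_ge_cutoff"),
        met = rbind(data$infarct_class == "CMCA", chads2 >= cutoffs$chads2)
      )
      if (score == "mortality2") {
        base$component <- c(base$component, "nihss_peak5_ge_cutoff")
        base$met <- rbind(base$met,
                          peak_nihss(data, cutoffs$nihss_window) >= cutoffs$nihss_peak)
      }
      k <- length(base$component)
      tibble(
        patient_id = rep(data$patient_id, each = k),
        score = score,
        component = rep(base$component, times = nrow(data)),
        met = as.vector(base$met),
        points = 1L
      )
    }
  )
  cutoff <- switch(score, chads2 = cutoffs$chads2, cmca = cutoffs$cmca,
                   mortality1 = cutoffs$mortality1, mortality2 = cutoffs$mortality2)
  comp |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(total = as.integer(sum(.data$points[.data$met])),
                  cutoff = as.integer(cutoff),
                  positive = .data$total >= .data$cutoff) |>
    dplyr::ungroup()
}
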