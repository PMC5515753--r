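#' Parameters of the synthetic LHI cohort generator
#'
#' Fully parameterizes [simulate_cohort()]. The defaults emulate the
#' marginal structure of a published 77-patient large-hemispheric-
#' infarction cohort: 42.9% complete MCA infarctions; per-group
#' prevalences of the early CT signs (hyperdense MCA sign 54.55% / 25%,
#' early brain edema 54.55% / 29.55%, >1/3 hypodensity 48.8% / 15.9% for
#' CMCA / IMCA respectively); group NIHSS means of 20.3 / 15.6 at
#' admission and 20.8 / 14.6 at day 5; and an in-hospital mortality,
#' generated from a logistic model on the mortality-score-2 total,
#' calibrated to about 11.7% overall. Vascular risk-factor prevalences
#' (shared by both groups, as the groups did not differ significantly)
#' are plausible values for an elderly stroke cohort; only hypertension
#' (68.8%) is pinned to a published marginal.
#'
#' @param n Cohort size (default 77).
#' @param p_cmca Probability of complete MCA infarction (default 0.429).
#' @param prev_cmca,prev_imca Named vectors of per-group Bernoulli
#'   prevalences for the binary fields (CT signs, risk factors,
#'   thrombolysis, craniectomy).
#' @param p_male Probability of male sex (default 41/77).
#' @param age_mean,age_sd,age_range Normal age model, rounded and clipped
#'   to `age_range` (defaults 70.7, 12.6, \[40, 94\]).
#' @param nihss_admission_mean,nihss_admission_sd Named (`cmca`, `imca`)
#'   admission-NIHSS normal parameters; draws are rounded and clipped to
#'   \[0, 42\].
#' @param nihss_day5_mean Named (`cmca`, `imca`) target day-5 means. Day-5
#'   NIHSS is generated as admission NIHSS plus a group-specific normal
#'   increment whose mean is `nihss_day5_mean - nihss_admission_mean`, so
#'   stroke in progression arises organically.
#' @param nihss_delta_sd Standard deviation of the day-5 increment.
#' @param p_day5_missing Probability a survivor lacks a day-5 NIHSS.
#' @param mortality_intercept,mortality_coef Logistic in-hospital
#'   mortality model: `P(death) = plogis(intercept + coef * MS2)` where
#'   MS2 is the patient's mortality-score-2 total. The default intercept
#'   is calibrated so overall mortality under the default parameters is
#'   about 0.117.
#' @param p_stroke_related_death Fraction of in-hospital deaths that are
#'   stroke related.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(
    n = 77,
    p_cmca = 0.429,
    prev_cmca = c(hypodensity_gt_one_third = 0.488, hmcas = 0.5455,
                  brain_edema = 0.5455, chf = 0.15, hypertension = 0.688,
                  diabetes = 0.35, prior_stroke_or_tia = 0.20,
                  atrial_fibrillation = 0.40, smoking = 0.35,
                  hypercholesterolemia = 0.30, coronary_artery_disease = 0.20,
                  thrombolysis = 0.15, craniectomy = 0.09),
    prev_imca = c(hypodensity_gt_one_third = 0.159, hmcas = 0.25,
                  brain_edema = 0.2955, chf = 0.15, hypertension = 0.688,
                  diabetes = 0.35, prior_stroke_or_tia = 0.20,
                  atrial_fibrillation = 0.40, smoking = 0.35,
                  hypercholesterolemia = 0.30, coronary_artery_disease = 0.20,
                  thrombolysis = 0.15, craniectomy = 0.0),
    p_male = 41 / 77,
    age_mean = 70.7, age_sd = 12.6, age_range = c(40, 94),
    nihss_admission_mean = c(cmca = 20.3, imca = 15.6),
    nihss_admission_sd = c(cmca = 5, imca = 5),
    nihss_day5_mean = c(cmca = 20.8, imca = 14.6),
    nihss_delta_sd = 3,
    p_day5_missing = 0,
    mortality_intercept = -3.50,
    mortality_coef = 1.5,
    p_stroke_related_death = 0.9) {
  params <- list(
    n = n, p_cmca = p_cmca, prev_cmca = prev_cmca, prev_imca = prev_imca,
    p_male = p_male, age_mean = age_mean, age_sd = age_sd,
    age_range = age_range,
    nihss_admission_mean = nihss_admission_mean,
    nihss_admission_sd = nihss_admission_sd,
    nihss_day5_mean = nihss_day5_mean, nihss_delta_sd = nihss_delta_sd,
    p_day5_missing = p_day5_missing,
    mortality_intercept = mortality_intercept,
    mortality_coef = mortality_coef,
    p_stroke_related_death = p_stroke_related_death
  )
  validate_cohort_params(params)
  structure(params, class = "cohort_params")
}

validate_cohort_params <- function(p) {
  probs <- c(p$p_cmca, p$prev_cmca, p$prev_imca, p$p_male, p$p_day5_missing,
             p$p_stroke_related_death)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (p$n < 1) abort("n must be >= 1")
  if (any(c(p$age_sd, p$nihss_admission_sd, p$nihss_delta_sd) <= 0)) {
    abort("standard deviations must be > 0")
  }
  needed <- setdiff(c(cohort_binary_fields(), "hypodensity_gt_one_third",
                      "hmcas", "brain_edema", "thrombolysis", "craniectomy"),
                    c(names(p$prev_cmca)))
  if (length(needed) > 0) {
    abort(paste0("prev_cmca is missing prevalences for: ",
                 paste(needed, collapse = ", ")))
  }
  if (!setequal(names(p$prev_cmca), names(p$prev_imca))) {
    abort("prev_cmca and prev_imca must name the same fields")
  }
  invisible(p)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a synthetic LHI cohort
#'
#' Draws a cohort of `params$n` patients with the structure described in
#' [cohort_params()]: group membership Bernoulli(`p_cmca`); CMCA patients
#' involve all three MCA territories, IMCA patients two territories with
#' a territory fraction uniform in \[0.5, 0.95\]; binary fields are
#' conditionally independent given group; NIHSS values are rounded,
#' clipped normals; in-hospital death follows the logistic model on the
#' mortality-score-2 total. Generation is a pure function of
#' (`params`, `seed`): the same pair always yields the identical cohort.
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer seed. The caller's RNG state is left untouched.
#'   `NULL` (default) consumes the ambient RNG stream.
#' @return A validated cohort tibble (see [cohort_columns()]).
#' @examples
#' cohort <- simulate_cohort(seed = 42)
#' dplyr::count(classify_infarct(cohort), infarct_class)
#' @export
simulate_cohort <- function(params = cohort_params(), seed = NULL) {
  validate_cohort_params(params)
  with_seed(seed, {
    n <- params$n
    is_cmca <- rbinom(n, 1, params$p_cmca) == 1
    grp <- ifelse(is_cmca, "cmca", "imca")

    territories <- character(n)
    territories[is_cmca] <- "deep;superior;posterior"
    if (any(!is_cmca)) {
      pairs <- utils::combn(mca_territories(), 2)
      pick <- sample.int(ncol(pairs), sum(!is_cmca), replace = TRUE)
      territories[!is_cmca] <- apply(pairs[, pick, drop = FALSE], 2, paste,
                                     collapse = ";")
    }
    mca_fraction <- ifelse(is_cmca, runif(n, 0.85, 1.0), runif(n, 0.5, 0.95))

    draw_bin <- function(field) {
      p <- ifelse(is_cmca, params$prev_cmca[[field]], params$prev_imca[[field]])
      rbinom(n, 1, p) == 1
    }
    bins <- lapply(names(params$prev_cmca), draw_bin)
    names(bins) <- names(params$prev_cmca)

    age <- as.integer(pmin(pmax(round(rnorm(n, params$age_mean, params$age_sd)),
                                params$age_range[1]), params$age_range[2]))
    adm <- as.integer(pmin(pmax(round(
      rnorm(n, params$nihss_admission_mean[grp], params$nihss_admission_sd[grp])
    ), 0), 42))
    delta_mean <- params$nihss_day5_mean[grp] - params$nihss_admission_mean[grp]
    day5 <- as.integer(pmin(pmax(round(
      adm + rnorm(n, delta_mean, params$nihss_delta_sd)
    ), 0), 42))

    cohort <- tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      age = age,
      sex = ifelse(rbinom(n, 1, params$p_male) == 1, "male", "female"),
      chf = bins$chf, hypertension = bins$hypertension,
      diabetes = bins$diabetes,
      prior_stroke_or_tia = bins$prior_stroke_or_tia,
      atrial_fibrillation = bins$atrial_fibrillation,
      smoking = bins$smoking,
      hypercholesterolemia = bins$hypercholesterolemia,
      coronary_artery_disease = bins$coronary_artery_disease,
      nihss_admission = adm, nihss_day5 = day5,
      hypodensity_gt_one_third = bins$hypodensity_gt_one_third,
      hmcas = bins$hmcas, brain_edema = bins$brain_edema,
      territories = territories, mca_fraction = mca_fraction,
      died_in_hospital = FALSE, stroke_related_death = FALSE,
      thrombolysis = bins$thrombolysis, craniectomy = bins$craniectomy
    )

    chads2 <- cohort$chf + cohort$hypertension + (cohort$age >= 75) +
      cohort$diabetes + 2L * cohort$prior_stroke_or_tia
    ms2 <- is_cmca + (chads2 >= 4) + (pmax(adm, day5) >= 26)
    p_death <- plogis(params$mortality_intercept + params$mortality_coef * ms2)
    died <- rbinom(n, 1, p_death) == 1
    cohort$died_in_hospital <- died
    cohort$stroke_related_death <- died &
      rbinom(n, 1, params$p_stroke_related_death) == 1

    if (params$p_day5_missing > 0) {
      drop5 <- !died & rbinom(n, 1, params$p_day5_missing) == 1
      cohort$nihss_day5[drop5] <- NA_integer_
    }
    validate_cohort(cohort, action = "error")
    cohort
  })
}

#' Recover generator parameters from a cohort
#'
#' Empirical counterpart of [cohort_params()]: the CMCA group fraction,
#' per-group prevalence of every binary field, per-group NIHSS moments,
#' and mortality rates, in long format for direct comparison with the
#' generating parameters. With only one group present, the other group's
#' rows are returned with `NA` estimates (explicit missingness) rather
#' than dropped.
#'
#' @param data A cohort data frame.
#' @return A tibble with columns `parameter`, `group` (`all`, `cmca`,
#'   `imca`), `estimate`, `n` (the number of records the estimate used).
#' @export
recover_params <- function(data) {
  if (nrow(data) == 0) abort("cohort must be non-empty")
  data <- classify_infarct(data)
  is_cmca <- data$infarct_class == "CMCA"
  groups <- list(cmca = data[is_cmca, ], imca = data[!is_cmca, ])
  bin_fields <- c(cohort_binary_fields(), "hypodensity_gt_one_third", "hmcas",
                  "brain_edema", "thrombolysis", "craniectomy")

  est <- function(d, parameter, value) {
    tibble(parameter = parameter,
           estimate = if (nrow(d) > 0) value else NA_real_,
           n = nrow(d))
  }
  per_group <- purrr::imap(groups, function(d, g) {
    rows <- dplyr::bind_rows(
      purrr::map(bin_fields, function(f) est(d, paste0("prev_", f), mean(d[[f]]))),
      est(d, "nihss_admission_mean", mean(d$nihss_admission)),
      est(d, "nihss_admission_sd", sd(d$nihss_admission)),
      est(d, "nihss_day5_mean", mean(d$nihss_day5, na.rm = TRUE)),
      est(d, "nihss_day5_sd", sd(d$nihss_day5, na.rm = TRUE)),
      est(d, "mortality", mean(d$died_in_hospital)),
      est(d, "age_mean", mean(d$age))
    )
    dplyr::mutate(rows, group = g, .after = "parameter")
  })
  dplyr::bind_rows(
    tibble(parameter = c("p_cmca", "p_male", "mortality"), group = "all",
           estimate = c(mean(is_cmca), mean(data$sex == "male"),
                        mean(data$died_in_hospital)),
           n = nrow(data)),
    per_group$cmca, per_group$imca
  )
}
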