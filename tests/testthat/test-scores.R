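test_that("infarct classification follows territory count then fraction", {
  d <- tibble::tibble(
    territories = c("deep;superior;posterior", "deep;superior", "deep",
                    "deep;superior;posterior", "superior;posterior", ""),
    mca_fraction = c(1.0, 0.6, 0.3, 0.1, 0.5, 0.9)
  )
  cls <- classify_infarct(d)$infarct_class
  expect_equal(as.character(cls),
               c("CMCA", "IMCA", "NOT_LHI", "CMCA", "IMCA", "IMCA"))
  # CMCA depends only on the territory set, never on the fraction
  expect_equal(as.character(cls[4]), "CMCA")
  # the half-territory boundary is inclusive
  expect_equal(as.character(cls[5]), "IMCA")
  expect_error(classify_infarct(tibble::tibble(territories = "deep;lateral",
                                               mca_fraction = 0.7)),
               "invalid territory")
})

test_that("CHADS2 totals enumerate exactly {0..6} with double-weighted prior stroke", {
  combos <- expand.grid(chf = c(FALSE, TRUE), ht = c(FALSE, TRUE),
                        old = c(FALSE, TRUE), dm = c(FALSE, TRUE),
                        ps = c(FALSE, TRUE))
  cohort <- do.call(make_cohort, purrr::pmap(combos, function(chf, ht, old, dm, ps) {
    make_patient(chf = chf, hypertension = ht, age = if (old) 80L else 60L,
                 diabetes = dm, prior_stroke_or_tia = ps)
  }))
  got <- score_patients(cohort)$chads2
  expected <- with(combos, chf + ht + old + dm + 2L * ps)
  expect_equal(got, as.integer(expected))
  expect_setequal(unique(got), 0:6)
  # the age-75 boundary is inclusive
  expect_equal(score_patients(make_patient(age = 75L))$chads2, 1L)
  expect_equal(score_patients(make_patient(age = 74L))$chads2, 0L)
})

test_that("stroke in progression needs a 2-point NIHSS rise or stroke-related death", {
  expect_true(stroke_in_progression(make_patient(nihss_admission = 15L,
                                                 nihss_day5 = 17L)))
  expect_false(stroke_in_progression(make_patient(nihss_admission = 15L,
                                                  nihss_day5 = 16L)))
  expect_true(stroke_in_progression(make_patient(
    nihss_admission = 20L, nihss_day5 = NA_integer_,
    died_in_hospital = TRUE, stroke_related_death = TRUE)))
  # a death not attributed to stroke does not by itself qualify
  expect_false(stroke_in_progression(make_patient(
    nihss_admission = 20L, nihss_day5 = 20L, died_in_hospital = TRUE)))
  expect_warning(
    out <- stroke_in_progression(make_patient(nihss_day5 = NA_integer_)),
    "day-5"
  )
  expect_false(out)
})

test_that("CMCA score totals match the five-component sum over all combinations", {
  combos <- expand.grid(hypo = c(FALSE, TRUE), hmcas = c(FALSE, TRUE),
                        edema = c(FALSE, TRUE), severe = c(FALSE, TRUE),
                        sip = c(FALSE, TRUE))
  cohort <- do.call(make_cohort, purrr::pmap(combos, function(hypo, hmcas, edema, severe, sip) {
    make_patient(hypodensity_gt_one_third = hypo, hmcas = hmcas,
                 brain_edema = edema,
                 nihss_admission = if (severe) 17L else 10L,
                 nihss_day5 = if (severe) 17L else 10L + if (sip) 2L else 0L,
                 stroke_related_death = severe & sip,
                 died_in_hospital = severe & sip)
  }))
  sp <- score_patients(cohort)
  expected <- with(combos, hypo + hmcas + edema + severe + sip)
  expect_equal(sp$cmca_score, as.integer(expected))
  expect_setequal(unique(sp$cmca_score), 0:5)
  expect_equal(sp$cmca_positive, expected >= 2)
  # admission threshold 17 is inclusive; one met component is not positive
  one <- score_patients(make_patient(nihss_admission = 17L, nihss_day5 = 17L))
  expect_equal(one$cmca_score, 1L)
  expect_false(one$cmca_positive)
  two <- score_patients(make_patient(nihss_admission = 17L, nihss_day5 = 17L,
                                     hmcas = TRUE))
  expect_equal(two$cmca_score, 2L)
  expect_true(two$cmca_positive)
})

test_that("mortality scores enumerate their ranges with inclusive boundaries", {
  combos <- expand.grid(cmca = c(FALSE, TRUE), chads_hi = c(FALSE, TRUE),
                        peak_hi = c(FALSE, TRUE))
  cohort <- do.call(make_cohort, purrr::pmap(combos, function(cmca, chads_hi, peak_hi) {
    make_patient(
      territories = if (cmca) "deep;superior;posterior" else "deep;superior",
      chf = chads_hi, hypertension = chads_hi, diabetes = chads_hi,
      prior_stroke_or_tia = FALSE, age = if (chads_hi) 80L else 60L,
      nihss_admission = 20L, nihss_day5 = if (peak_hi) 26L else 20L
    )
  }))
  sp <- score_patients(cohort)
  expect_equal(sp$mortality1, as.integer(combos$cmca + combos$chads_hi))
  expect_equal(sp$mortality2,
               as.integer(combos$cmca + combos$chads_hi + combos$peak_hi))
  expect_setequal(unique(sp$mortality1), 0:2)
  expect_setequal(unique(sp$mortality2), 0:3)
  expect_equal(sp$mortality1_positive, sp$mortality1 >= 1)
  expect_equal(sp$mortality2_positive, sp$mortality2 >= 2)
  # published readings: CMCA alone is mortality-1 positive; IMCA with
  # CHADS2 >= 4 is mortality-1 positive; IMCA with CHADS2 3 is not
  m1 <- function(p) score_patients(p)$mortality1
  expect_equal(m1(make_patient(territories = "deep;superior;posterior",
                               hypertension = TRUE, diabetes = TRUE)), 1L)
  imca4 <- make_patient(chf = TRUE, hypertension = TRUE, diabetes = TRUE,
                        age = 80L)
  expect_equal(m1(imca4), 1L)
  expect_true(score_patients(imca4)$mortality1_positive)
  imca3 <- make_patient(chf = TRUE, hypertension = TRUE, diabetes = TRUE)
  expect_equal(m1(imca3), 0L)
  expect_false(score_patients(imca3)$mortality1_positive)
})

test_that("mortality scores are not applicable below the LHI threshold", {
  small <- make_patient(territories = "deep", mca_fraction = 0.3)
  sp <- score_patients(small)
  expect_equal(as.character(sp$infarct_class), "NOT_LHI")
  expect_true(is.na(sp$mortality1))
  expect_true(is.na(sp$mortality2))
  expect_false(is.na(sp$chads2))
  expect_error(score_breakdown(small, "mortality1"), "LHI")
  expect_error(score_breakdown(small, "mortality2"), "LHI")
})

test_that("breakdown totals equal the sum of met component points", {
  set.seed(41)
  cohort <- simulate_cohort(cohort_params(n = 60), seed = 41)
  sp <- score_patients(cohort)
  for (sc in c("chads2", "cmca", "mortality1", "mortality2")) {
    bd <- suppressWarnings(score_breakdown(cohort, sc))
    totals <- bd |>
      dplyr::distinct(patient_id, total, cutoff, positive)
    recomputed <- bd |>
      dplyr::group_by(patient_id) |>
      dplyr::summarise(s = sum(points[met]), .groups = "drop")
    joined <- dplyr::left_join(totals, recomputed, by = "patient_id")
    expect_equal(joined$total, as.integer(joined$s))
    expect_equal(joined$positive, joined$total >= joined$cutoff)
    col <- c(chads2 = "chads2", cmca = "cmca_score",
             mortality1 = "mortality1", mortality2 = "mortality2")[[sc]]
    expect_equal(totals$total[match(sp$patient_id, totals$patient_id)],
                 sp[[col]])
  }
  # CHADS2 carries the only non-unit weight
  bd <- score_breakdown(cohort, "chads2")
  expect_equal(unique(bd$points[bd$component == "prior_stroke_or_tia"]), 2L)
  expect_true(all(bd$points[bd$component != "prior_stroke_or_tia"] == 1L))
})

test_that("raising any component never lowers a score or flips positivity off", {
  set.seed(7)
  flags <- c("chf", "hypertension", "diabetes", "prior_stroke_or_tia",
             "hypodensity_gt_one_third", "hmcas", "brain_edema")
  score_cols <- c("chads2", "cmca_score", "mortality1", "mortality2")
  pos_cols <- paste0(c("chads2", "cmca", "mortality1", "mortality2"), "_positive")
  for (i in 1:25) {
    base <- simulate_cohort(cohort_params(n = 1), seed = i)
    before <- suppressWarnings(score_patients(base))
    f <- sample(flags, 1)
    if (base[[f]]) next
    bumped <- base
    bumped[[f]] <- TRUE
    after <- suppressWarnings(score_patients(bumped))
    for (col in score_cols) expect_gte(after[[col]], before[[col]])
    for (col in pos_cols) expect_false(before[[col]] & !after[[col]])
  }
})

test_that("the day5-only NIHSS window is available and falls back to admission", {
  day5_cut <- score_cutoffs(nihss_window = "day5")
  p <- make_patient(nihss_admission = 30L, nihss_day5 = 20L)
  expect_equal(score_patients(p)$nihss_peak5, 30L)             # peak window
  expect_equal(score_patients(p, day5_cut)$nihss_peak5, 20L)   # day-5 only
  gone <- make_patient(nihss_admission = 30L, nihss_day5 = NA_integer_,
                       died_in_hospital = TRUE, stroke_related_death = TRUE)
  expect_equal(score_patients(gone, day5_cut)$nihss_peak5, 30L)
})
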