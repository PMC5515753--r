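# Independent oracles and a one-row patient factory used across the suite.

# Single-patient cohort row with benign defaults; override any field.
make_patient <- function(...) {
  row <- tibble::tibble(
    patient_id = "P1", age = 60L, sex = "female",
    chf = FALSE, hypertension = FALSE, diabetes = FALSE,
    prior_stroke_or_tia = FALSE, atrial_fibrillation = FALSE,
    smoking = FALSE, hypercholesterolemia = FALSE,
    coronary_artery_disease = FALSE,
    nihss_admission = 10L, nihss_day5 = 10L,
    hypodensity_gt_one_third = FALSE, hmcas = FALSE, brain_edema = FALSE,
    territories = "deep;superior", mca_fraction = 0.6,
    died_in_hospital = FALSE, stroke_related_death = FALSE,
    thrombolysis = FALSE, craniectomy = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) row[[nm]] <- dots[[nm]]
  row
}

make_cohort <- function(...) {
  rows <- list(...)
  out <- dplyr::bind_rows(rows)
  out$patient_id <- sprintf("P%03d", seq_len(nrow(out)))
  out
}

# AUC as Mann-Whitney concordance probability, ties counted 1/2,
# by brute force over every positive-negative pair.
concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Best Youden cutoff by exhaustive scan over every distinct score value,
# recomputing sensitivity/specificity by direct counting.
scan_best_cutoff <- function(scores, labels) {
  best <- NULL
  for (t in sort(unique(scores))) {
    sens <- sum(scores >= t & labels == 1) / sum(labels == 1)
    spec <- sum(scores < t & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12) ||
        (abs(j - best$j) <= 1e-12 && abs(sens - best$sens) <= 1e-12 &&
         t < best$t)) {
      best <- list(t = t, j = j, sens = sens, spec = spec)
    }
  }
  best
}

# Two-sided Fisher p by explicit enumeration of every table with the
# observed margins, using factorial arithmetic (not dhyper).
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  tab_prob <- function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, tab_prob, numeric(1))
  p_obs <- tab_prob(a)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Pooled two-sample t evaluated directly from the closed form.
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(statistic = stat,
       p = 2 * pt(abs(stat), df = nx + ny - 2, lower.tail = FALSE))
}
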