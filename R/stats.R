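#' Empirical ROC curve with AUC and Youden-optimal cutoff
#'
#' Builds the empirical ROC of a score against a binary outcome using the
#' inclusive positive-prediction rule (predict positive when
#' score >= threshold). One point is produced per distinct score value,
#' plus the degenerate all-negative point (sensitivity 0, specificity 1)
#' at an infinite threshold. The AUC is computed by trapezoidal
#' integration, which for a step ROC equals the Mann-Whitney concordance
#' probability (ties counted 1/2). The stored best cutoff maximizes
#' Youden's J = sensitivity + specificity - 1, ties broken toward higher
#' sensitivity and then the lower threshold.
#'
#' @param data A data frame.
#' @param score Column with the ordinal score (tidy-eval).
#' @param label Column with the binary outcome (tidy-eval); logical, or
#'   0/1 numeric.
#' @return An object of class `roc_result`: a list with `points` (tibble
#'   of `threshold`, `sensitivity`, `specificity`, thresholds strictly
#'   decreasing), `auc`, `best_cutoff`, `sens_at_best`, `spec_at_best`,
#'   `n_pos`, `n_neg`. Methods: [tidy()], [glance()], [autoplot()].
#' @examples
#' d <- tibble::tibble(s = c(1, 2, 3, 4), y = c(0, 0, 1, 1))
#' roc <- roc_curve(d, s, y)
#' glance(roc)
#' @export
roc_curve <- function(data, score, label) {
  s <- eval_tidy(enquo(score), data)
  y <- as_binary_label(eval_tidy(enquo(label), data))
  if (length(s) != length(y) || length(s) < 2) {
    abort("score and label must have equal length >= 2")
  }
  if (anyNA(s) || anyNA(y)) abort("score and label must not contain NA")
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    abort("degenerate input: need at least one positive and one negative label")
  }
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(s >= t & y) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(s < t & !y) / n_neg, numeric(1))
  points <- tibble(threshold = thr, sensitivity = sens, specificity = spec)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  res <- structure(
    list(points = points, auc = auc, best_cutoff = NA_real_,
         sens_at_best = NA_real_, spec_at_best = NA_real_,
         n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
  best <- best_cutoff_row(res)
  res$best_cutoff <- best$threshold
  res$sens_at_best <- best$sensitivity
  res$spec_at_best <- best$specificity
  res
}

as_binary_label <- function(y) {
  if (is.logical(y)) return(y)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (!all(y %in% c(0, 1), na.rm = TRUE)) {
    abort("label must be logical or 0/1")
  }
  y == 1
}

best_cutoff_row <- function(roc) {
  pts <- roc$points[is.finite(roc$points$threshold), , drop = FALSE]
  j <- pts$sensitivity + pts$specificity - 1
  # J values that are mathematically equal can differ in the last ulp, so
  # ties are detected with a small absolute tolerance
  cand <- which(j >= max(j) - 1e-9)
  cand <- cand[pts$sensitivity[cand] >= max(pts$sensitivity[cand]) - 1e-9]
  cand <- cand[which.min(pts$threshold[cand])]
  pts[cand, , drop = FALSE]
}

#' @rdname roc_curve
#' @param roc A `roc_result` object.
#' @return `best_cutoff()`: the threshold maximizing Youden's J.
#' @export
best_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  roc$best_cutoff
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("Empirical ROC: %d positives / %d negatives\n", x$n_pos, x$n_neg))
  cat(sprintf("  AUC %.3f; best cutoff %g (Youden), sensitivity %.3f, specificity %.3f\n",
              x$auc, x$best_cutoff, x$sens_at_best, x$spec_at_best))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$points

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, best_cutoff = x$best_cutoff,
         sensitivity = x$sens_at_best, specificity = x$spec_at_best,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' Uses the same inclusive rule as [roc_curve()]: predicted positive when
#' score >= cutoff.
#'
#' @inheritParams roc_curve
#' @param cutoff The decision threshold.
#' @return A one-row tibble: `cutoff`, `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `specificity` (proportions in \[0, 1\]).
#' @export
sens_spec <- function(data, score, label, cutoff) {
  s <- eval_tidy(enquo(score), data)
  y <- as_binary_label(eval_tidy(enquo(label), data))
  if (sum(y) == 0 || sum(!y) == 0) {
    abort("need at least one positive and one negative label")
  }
  pred <- s >= cutoff
  tp <- sum(pred & y); fp <- sum(pred & !y)
  fn <- sum(!pred & y); tn <- sum(!pred & !y)
  tibble(cutoff = cutoff, tp = tp, fp = fp, fn = fn, tn = tn,
         sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

as_table2x2 <- function(tab) {
  if (is.data.frame(tab)) tab <- as.matrix(tab)
  if (!is.matrix(tab) || !all(dim(tab) == c(2, 2))) {
    abort("expected a 2x2 matrix of counts (rows = group, columns = outcome)")
  }
  if (any(tab < 0) || anyNA(tab)) abort("counts must be nonnegative and complete")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("undefined test: a margin of the 2x2 table is zero")
  }
  tab
}

#' Build a 2x2 contingency table
#'
#' @param a,b Counts in the first row (group 1: outcome present / absent).
#' @param c,d Counts in the second row.
#' @return A 2x2 integer matrix.
#' @export
table2x2 <- function(a, b, c, d) {
  matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
         dimnames = list(group = c("g1", "g2"), outcome = c("yes", "no")))
}

#' Pearson chi-square test for a 2x2 table
#'
#' The classical statistic
#' \eqn{\chi^2 = n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}
#' with 1 degree of freedom and, by default, no continuity correction
#' (the form that reproduces the published group-comparison p-values from
#' reconstructed counts). The Yates-corrected variant is available behind
#' `correct = TRUE`.
#'
#' @param tab A 2x2 count matrix, e.g. from [table2x2()].
#' @param correct Apply the Yates continuity correction?
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' chi2_test_2x2(table2x2(11, 22, 6, 38)) # prints as P = .04
#' @export
chi2_test_2x2 <- function(tab, correct = FALSE) {
  tab <- as_table2x2(tab)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  stat <- n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  tibble::new_tibble(
    list(statistic = stat, df = 1L,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE)),
    nrow = 1L)
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by full enumeration: with all margins fixed, sums the
#' hypergeometric probabilities of every table no more probable than the
#' observed one (small relative tolerance for floating-point ties, as is
#' conventional).
#'
#' @inheritParams chi2_test_2x2
#' @return A one-row tibble: `p_value`.
#' @export
fisher_test_2x2 <- function(tab) {
  tab <- as_table2x2(tab)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  tibble::new_tibble(
    list(p_value = min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))),
    nrow = 1L)
}

#' Two-sample t test
#'
#' Classical pooled-variance Student t by default (two-sided, n1 + n2 - 2
#' degrees of freedom), with the Welch unequal-variance form behind
#' `var_equal = FALSE`. Two identical constant samples give statistic 0
#' and p = 1; constant samples with different means give an infinite
#' statistic and p = 0.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param var_equal Pool the variances (Student) or not (Welch)?
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_x`,
#'   `mean_y`.
#' @export
t_test2 <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("each sample needs >= 2 values")
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- var(x); vy <- var(y)
  if (var_equal) {
    df <- nx + ny - 2
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  if (se == 0) {
    stat <- if (mx == my) 0 else sign(mx - my) * Inf
    p <- if (mx == my) 1 else 0
  } else {
    stat <- (mx - my) / se
    p <- 2 * pt(abs(stat), df = df, lower.tail = FALSE)
  }
  tibble::new_tibble(
    list(statistic = stat, df = df, p_value = p, mean_x = mx, mean_y = my),
    nrow = 1L)
}

#' Percentage with half-up rounding
#'
#' `100 * k / n` rounded half-up (the reporting convention of clinical
#' tables, e.g. 33/77 prints as 42.9).
#'
#' @param k Numerator count(s), `0 <= k <= n`.
#' @param n Denominator count(s), `> 0`.
#' @param decimals Decimal places (default 1).
#' @return Numeric percentage(s).
#' @examples
#' pct(33, 77) # 42.9
#' pct(9, 77)  # 11.7
#' @export
pct <- function(k, n, decimals = 1) {
  if (any(n <= 0)) abort("undefined percentage: n must be > 0")
  if (any(k < 0 | k > n)) abort("k must satisfy 0 <= k <= n")
  x <- 100 * k / n
  f <- 10^decimals
  floor(x * f + 0.5) / f
}
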