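#' Plot an empirical ROC curve
#'
#' Step ROC in 1 - specificity / sensitivity space with the chance
#' diagonal and the Youden-optimal operating point marked.
#'
#' @param object A `roc_result` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  pts <- object$points
  pts <- pts[order(1 - pts$specificity, pts$sensitivity), ]
  best <- pts[is.finite(pts$threshold) & pts$threshold == object$best_cutoff, ]
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(data = best, colour = "red", size = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f; cutoff %g", object$auc,
                                  object$best_cutoff)) +
    ggplot2::theme_minimal()
}

#' Plot all ROC analyses of a cohort analysis
#'
#' One curve per score (CMCA score vs CMCA membership; mortality scores
#' vs in-hospital death), with AUCs in the legend.
#'
#' @param object A `cohort_analysis` from [analyze_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_analysis <- function(object, ...) {
  if (length(object$rocs) == 0) abort("no ROC analyses available to plot")
  pts <- purrr::imap(object$rocs, function(r, nm) {
    dplyr::mutate(r$roc$points,
                  score = sprintf("%s (AUC %.2f)", nm, r$roc$auc))
  }) |> dplyr::bind_rows()
  pts <- pts[order(pts$score, 1 - pts$specificity, pts$sensitivity), ]
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity,
                                    colour = .data$score)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
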