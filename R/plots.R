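#' Plot per-gene selection frequencies
#'
#' Bar chart of the top selection frequencies from stability selection,
#' with the consensus threshold drawn as a dashed line.
#'
#' @param object A `stability_result`.
#' @param top_n How many genes to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stability_result
#' @export
autoplot.stability_result <- function(object, top_n = 20, ...) {
  d <- head(object$stability, top_n)
  d$gene <- factor(d$gene, levels = rev(d$gene))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency, y = .data$gene)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$params$frequency_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "selection frequency", y = NULL,
                  title = "Stability-selection frequencies") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves
#'
#' @param object A [km_logrank()] fit.
#' @param ... Unused.
#' @return A ggplot object with one step curve per group and the log-rank
#'   p-value in the subtitle.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  d <- tidy(object)
  d0 <- dplyr::bind_rows(
    tibble(group = factor(names(object$n_per_group),
                          levels = levels(d$group)),
           time = 0, survival = 1),
    d[c("group", "time", "survival")]
  )
  ggplot2::ggplot(d0, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "survival probability",
                  subtitle = paste0("log-rank p = ",
                                    format(object$logrank_p, digits = 3))) +
    ggplot2::theme_minimal()
}

#' ROC curve for a score against a binary outcome
#'
#' @param scores Numeric scores.
#' @param outcome Binary outcome (0/1).
#' @return A ggplot object; the AUC is shown in the subtitle.
#' @export
plot_roc <- function(scores, outcome) {
  r <- pROC::roc(response = outcome, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  d <- tibble(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = paste0("AUC = ",
                                    format(as.numeric(pROC::auc(r)), digits = 3))) +
    ggplot2::theme_minimal()
}

#' Plot the risk-score distribution with the classification cutoff
#'
#' @param profile A `risk_profile` from [score_cohort()].
#' @param cutoff Cutoff to draw (default: inferred from the risk classes).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(profile, cutoff = NULL) {
  cutoff <- cutoff %||% {
    hi <- profile$score[profile$risk_class == "high"]
    lo <- profile$score[profile$risk_class == "low"]
    if (length(hi)) (max(lo) + min(hi)) / 2 else max(lo)
  }
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$score,
                                        fill = .data$risk_class)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.8, position = "identity") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed") +
    ggplot2::labs(x = "classifier score", y = "samples") +
    ggplot2::theme_minimal()
}
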