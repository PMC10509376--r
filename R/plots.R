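# ggplot2 displays for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object A `roc_curve` (from [youden_threshold()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate", y = "Sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Plot the model-size sweep of a cross-validation report
#'
#' Mean cross-validated metric against the keepX budget, with one-standard-
#' deviation ribbons across repeats.
#'
#' @param object A `cv_report`.
#' @param metric One of `"oer"`, `"auc"`, `"brier"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, metric = c("oer", "auc", "brier"), ...) {
  metric <- match.arg(metric)
  m <- object$metrics
  m$value <- m[[metric]]
  m$sd <- m[[paste0(metric, "_sd")]]
  ggplot2::ggplot(m, ggplot2::aes(x = .data$keepX, y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$sd,
                                      ymax = .data$value + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "keepX (features per component)",
                  y = sprintf("Mean cross-validated %s", toupper(metric))) +
    ggplot2::theme_minimal()
}

#' Plot feature-stability frequencies
#'
#' Selection frequency of each feature across cross-validation fits, in
#' decreasing order, with the low-stability cutoff marked.
#'
#' @param report A `cv_report`.
#' @param keepX Model size to display.
#' @param low_cutoff Stability cutoff line (default 0.5).
#' @param top_n Show at most this many features (default 100).
#' @return A ggplot.
#' @export
plot_stability <- function(report, keepX, low_cutoff = 0.5, top_n = 100) {
  st <- feature_stability(report, keepX, low_cutoff)
  st <- dplyr::arrange(st, dplyr::desc(.data$frequency))
  st <- utils::head(st, top_n)
  st$rank <- seq_len(nrow(st))
  ggplot2::ggplot(st, ggplot2::aes(x = .data$rank, y = .data$frequency,
                                   colour = .data$low_stability)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = low_cutoff, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "grey60"),
                                 name = "Low stability") +
    ggplot2::labs(x = "Feature rank", y = "Selection frequency",
                  title = sprintf("Feature stability (keepX = %d)", keepX)) +
    ggplot2::theme_minimal()
}

#' Plot predicted class probabilities
#'
#' @param object An `splsda_prediction` tibble.
#' @param ... Unused.
#' @return A ggplot of positive-class probabilities by thresholded call.
#' @method autoplot splsda_prediction
#' @export
autoplot.splsda_prediction <- function(object, ...) {
  pos <- attr(object, "positive_class")
  df <- tibble::as_tibble(object)
  df$prob <- df[[paste0("prob_", pos)]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class_threshold, y = .data$prob)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = "Thresholded call",
                  y = sprintf("P(%s)", pos)) +
    ggplot2::theme_minimal()
}
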