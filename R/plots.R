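#' Scatter plot of a cohort's ratio features by maturation class
#'
#' @param data Dataset table.
#' @param x,y Feature columns to plot.
#' @return A ggplot object.
#' @export
plot_cohort <- function(data, x = "C3", y = "C4") {
  .validate_dataset(data)
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data[[x]], y = .data[[y]],
    colour = factor(.data$Maturation,
                    labels = c("pre-peak", "peak", "post-peak")))) +
    ggplot2::geom_point(alpha = 0.6, size = 1.5) +
    ggplot2::labs(colour = "Maturation") +
    ggplot2::theme_minimal()
}

#' @describeIn compute_metrics Confusion-matrix heatmap.
#' @param object A `cvd_metrics` object.
#' @param ... Unused.
#' @export
autoplot.cvd_metrics <- function(object, ...) {
  df <- as.data.frame.table(object$confusion, responseName = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted class", y = "True class") +
    ggplot2::theme_minimal()
}

#' @describeIn feature_importance Bar chart of permutation importances.
#' @param object A `cvd_importance` tibble.
#' @param ... Unused.
#' @export
autoplot.cvd_importance <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$importance),
    y = .data$importance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$importance - .data$sd,
      ymax = .data$importance + .data$sd), width = 0.2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Accuracy drop under permutation") +
    ggplot2::theme_minimal()
}

#' @describeIn cutoff_report Feature distributions by class with cutoff
#'   lines.
#' @param object A `cvd_cutoffs` object.
#' @param data The dataset table the cutoffs were derived from.
#' @param ... Unused.
#' @export
autoplot.cvd_cutoffs <- function(object, data, ...) {
  feats <- unique(object$cut_points$feature)
  long <- tidyr::pivot_longer(data[c(feats, "Maturation")],
                              dplyr::all_of(feats),
                              names_to = "feature", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$value,
    fill = factor(.data$Maturation,
                  labels = c("pre-peak", "peak", "post-peak")))) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.7, position = "identity") +
    ggplot2::geom_vline(data = object$cut_points,
                        ggplot2::aes(xintercept = .data$cut_point),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(fill = "Maturation", x = NULL) +
    ggplot2::theme_minimal()
}
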