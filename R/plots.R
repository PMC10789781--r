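#' Plot a radial layer profile
#'
#' Bar chart of the profile's metric (DMP frequency, mean |delta M|, mean
#' |logFC|, ...) across layers L1 (outer) to L5 (inner).
#'
#' @param object A `layer_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot layer_profile
#' @export
autoplot.layer_profile <- function(object, ...) {
  metric <- attr(object, "metric") %||% "value"
  value_col <- setdiff(names(object)[vapply(object, is.numeric, logical(1))],
                       c("n", "n_dmp", "n_background"))[1]
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$layer, y = .data[[value_col]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "nuclear layer (L1 outer - L5 inner)", y = metric) +
    ggplot2::theme_minimal()
}

#' Plot the permutation null against the observed statistic
#'
#' @param object A `perm_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perm_test
#' @export
autoplot.perm_test <- function(object, ...) {
  ggplot2::ggplot(tibble(null = object$null), ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "null DMP-in-DMR fraction",
                  subtitle = sprintf("observed %.3f, empirical p = %.3g",
                                     object$observed, object$empirical_p)) +
    ggplot2::theme_minimal()
}

#' Plot per-class mean logFC trajectories
#'
#' @param trajectory Output of [logfc_trajectory()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectory) {
  ggplot2::ggplot(trajectory$class_means,
                  ggplot2::aes(x = .data$timepoint, y = .data$mean_logfc,
                               colour = .data$class,
                               group = .data$class)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "timepoint", y = "mean logFC vs control") +
    ggplot2::theme_minimal()
}
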