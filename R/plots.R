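# ggplot2 methods for the package's result types.

#' Plot a tri-axial trace
#'
#' One facet per axis against time.
#'
#' @param object A trace tibble (class `accel_trace`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot accel_trace
#' @export
autoplot.accel_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("heave_g", "surge_g", "sway_g"),
                              names_to = "axis", values_to = "g") |>
    mutate(axis = sub("_g$", "", .data$axis))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$g)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "acceleration (g)")
}

#' Plot a confusion matrix as a heatmap
#'
#' Cell shade encodes the classification frequency; rows are true labels,
#' columns predictions.
#'
#' @param object A `conf_mat`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot conf_mat
#' @export
autoplot.conf_mat <- function(object, ...) {
  long <- tidy.conf_mat(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                     fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 2.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted", y = "true behaviour") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a fit's variable importance
#'
#' Scaled importance (percent of the top predictor) as horizontal bars.
#'
#' @param object An `rf_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rf_fit
#' @export
autoplot.rf_fit <- function(object, ...) {
  imp <- variable_importance(object)
  ggplot2::ggplot(imp, ggplot2::aes(
    x = .data$scaled_importance,
    y = stats::reorder(.data$predictor, .data$scaled_importance))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "scaled importance (%)", y = NULL)
}

#' Plot per-behaviour accuracy by device and resolution
#'
#' @param object An `experiment_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot experiment_report
#' @export
autoplot.experiment_report <- function(object, ...) {
  ggplot2::ggplot(object$accuracy_table,
                  ggplot2::aes(x = .data$accuracy, y = .data$behaviour,
                               fill = .data$device)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~resolution, scales = "free_y") +
    ggplot2::labs(x = "validation accuracy (%)", y = NULL)
}
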