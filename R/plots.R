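#' Plot tertile-binned grand-average curves
#'
#' One line per predictor bin (low / mid / high), faceted by component,
#' with the conventional evoked-response layout (time on the x axis).
#'
#' @param bins Tibble from [bin_by_predictor()].
#' @return A ggplot object.
#' @export
plot_binned_curves <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$time_ms, y = .data$amplitude,
                                     colour = .data$bin)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "Time (ms)", y = "Amplitude",
                  colour = "Predictor bin") +
    ggplot2::theme_minimal()
}

#' Plot the training cost trajectory of an MDL model
#'
#' @param object An `mdl_model`.
#' @param ... Unused.
#' @return A ggplot object showing total code length after initialization
#'   and after each epoch.
#' @export
autoplot.mdl_model <- function(object, ...) {
  d <- tibble::tibble(epoch = seq_along(object$cost_history) - 1,
                      total_cost_bits = object$cost_history)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$total_cost_bits)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Epoch", y = "Total code length (bits)") +
    ggplot2::theme_minimal()
}

#' Plot standardized coefficients of a stepwise fit
#'
#' @param object A `stepwise_fit`.
#' @param ... Unused.
#' @return A ggplot bar chart of standardized betas in selection order.
#' @export
autoplot.stepwise_fit <- function(object, ...) {
  d <- tidy(object)
  d$term <- factor(d$term, levels = d$term[order(d$step)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Standardized beta") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
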