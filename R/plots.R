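#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Plot a simulation trace
#'
#' Faceted monthly time series of the main simulated quantities: body
#' weight, condition index, voluntary DMI, ME intake, potential and
#' actual milk yield, daily gain and mobilization.
#'
#' @param object A `sim_trace` from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' ggplot2::autoplot(run_simulation(builtin_fixture("maize_lablab")))
#' @exportS3Method ggplot2::autoplot
autoplot.sim_trace <- function(object, ...) {
  long <- tidy.sim_trace(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "Monthly step", y = NULL,
                  title = "Simulated animal trajectory") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' Bar chart of the relative prediction error per parameter, shaded by
#' accuracy class, with the 10/20/30% class boundaries drawn as
#' reference lines.
#'
#' @param report A tibble from [model_evaluation()] or
#'   [evaluate_against_observed()].
#' @return A ggplot object.
#' @export
plot_evaluation <- function(report) {
  label_col <- setdiff(names(report),
                       c("n_pairs", "mbe", "rmsep", "rpe", "accuracy_class"))
  report$label <- if (length(label_col) > 0) {
    do.call(paste, c(report[label_col], sep = " / "))
  } else as.character(seq_len(nrow(report)))
  ggplot2::ggplot(report, ggplot2::aes(x = .data$label, y = .data$rpe,
                                       fill = .data$accuracy_class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(10, 20, 30), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Relative prediction error (% of observed mean)",
                  fill = "Accuracy") +
    ggplot2::theme_minimal()
}
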