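#' Histogram of line proportions against the theoretical distribution
#'
#' Plots the observed distribution of line-B (or C) proportions with the
#' theoretical density overlaid: a normal curve with mean 0.25 and the
#' standard deviation given by [theoretical_variance()] for the supplied
#' chromosome lengths.
#'
#' @param est Tibble of proportion estimates (one method).
#' @param lengths_morgan Chromosome map lengths in Morgan.
#' @param line `"B"` (default) or `"C"`.
#' @param binwidth Histogram bin width, default 0.01.
#' @return A ggplot object.
#' @export
plot_proportions <- function(est, lengths_morgan, line = c("B", "C"),
                             binwidth = 0.01) {
  line <- match.arg(line)
  col <- paste0("b_", line)
  td <- theoretical_variance(lengths_morgan)
  df <- tibble::tibble(b = est[[col]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth, fill = "grey70",
                            colour = "grey40") +
    ggplot2::stat_function(fun = stats::dnorm,
                           args = list(mean = td$mean, sd = td$sd),
                           colour = "red", linewidth = 0.8) +
    ggplot2::labs(x = sprintf("line %s proportion", line), y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a simulation-study summary
#'
#' Accuracy (or another metric) of each method per scenario, one panel per
#' evaluation reference.
#'
#' @param object A `sim_study` from [run_simulation_study()].
#' @param metric One of `"accuracy"`, `"slope"`, `"max_error"`, `"rmse"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sim_study
#' @export
autoplot.sim_study <- function(object, metric = "accuracy", ...) {
  stopifnot(metric %in% c("accuracy", "slope", "max_error", "rmse"))
  df <- object$summary
  df$scenario <- factor(df$scenario, levels = c("close", "distant", "unrelated"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data[[metric]],
                                   group = .data$method,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$reference),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(y = metric, x = "scenario") +
    ggplot2::theme_minimal()
}

#' Scatter plot of estimates against a reference
#'
#' @param est Estimates tibble (may contain several methods).
#' @param ref Reference tibble (single method).
#' @param line `"B"` (default) or `"C"`.
#' @return A ggplot object, one facet per method, with the identity line.
#' @export
plot_estimates_vs_reference <- function(est, ref, line = c("B", "C")) {
  line <- match.arg(line)
  col <- paste0("b_", line)
  joined <- dplyr::inner_join(
    dplyr::select(est, dplyr::all_of(c("animal", "method", col))),
    dplyr::select(ref, dplyr::all_of(c("animal", col))),
    by = "animal", suffix = c("_est", "_ref"))
  ggplot2::ggplot(joined, ggplot2::aes(x = .data[[paste0(col, "_est")]],
                                       y = .data[[paste0(col, "_ref")]])) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$method)) +
    ggplot2::labs(x = sprintf("estimated line %s proportion", line),
                  y = sprintf("reference line %s proportion", line)) +
    ggplot2::theme_minimal()
}
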