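#' Coefficient plot for a moderated gain model
#'
#' Forest-style plot of the model's coefficients with their BCa bootstrap
#' intervals (falling back to analytic OLS intervals if the bootstrap was
#' skipped). The intercept is omitted because it lives on a different
#' scale.
#'
#' @param object A `gain_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gain_model <- function(object, ...) {
  tab <- tidy(object)
  if (all(is.na(tab$conf.low))) tab <- tidy(object, conf_type = "ols")
  tab <- tab[tab$term != "(Intercept)", ]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate,
                                    y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Coefficient (95% CI)", y = NULL,
                  title = "EF gain model coefficients") +
    ggplot2::theme_minimal()
}

#' Modularity vs gain scatterplot by group
#'
#' The headline brain-behavior relationship: baseline modularity against
#' EF composite gain, one panel per intervention group, with an OLS line.
#'
#' @param data Cohort tibble with `modularity`, a gain column and `group`.
#' @param gain Name of the gain column (default `"ef_gain"`).
#' @return A ggplot object.
#' @export
plot_modularity_gain <- function(data, gain = "ef_gain") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$modularity, y = .data[[gain]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "Baseline modularity (Q)",
                  y = "EF gain (pre-test SD units)") +
    ggplot2::theme_minimal()
}

#' Modularity across density thresholds
#'
#' Per-subject Q as a function of graph density (cost), by partition
#' source, from a [cohort_modularity()] table.
#'
#' @param metrics Tibble with `subject_id`, `cost`, `source`, `Q`.
#' @return A ggplot object.
#' @export
plot_cost_curve <- function(metrics) {
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$cost, y = .data$Q,
                                        group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$source)) +
    ggplot2::scale_x_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = "Connection density (cost)", y = "Modularity (Q)") +
    ggplot2::theme_minimal()
}
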