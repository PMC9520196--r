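#' Plot a simulation trajectory
#'
#' Biomass of every species over the generations, coloured by initial
#' functional group, with line type by life strategy.
#'
#' @param object A `bq_sim` with trajectories.
#' @param log10 Plot biomass on a log10 axis (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bq_sim <- function(object, log10 = TRUE, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$generation, .data$biomass,
                                       group = .data$species_id,
                                       colour = .data$group,
                                       linetype = .data$strategy)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "Generation", y = "Biomass (ng)",
                  colour = "Functional group", linetype = "Life strategy") +
    ggplot2::theme_minimal()
  if (log10) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a scenario's diversity-function relationship
#'
#' Scatter of cumulative biomass production against final Shannon index
#' across replicates, optionally with the fitted logistic curve.
#'
#' @param object A `bq_scenario`.
#' @param fit Optional `bq_logistic` from [fit_logistic()] to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bq_scenario <- function(object, fit = NULL, ...) {
  d <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$shannon_final,
                                       .data$cumulative_biomass)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(x = "Shannon index (final)",
                  y = "Cumulative biomass production (ng)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xs <- seq(min(d$shannon_final, na.rm = TRUE),
              max(d$shannon_final, na.rm = TRUE), length.out = 200)
    curve <- tibble::tibble(
      shannon_final = xs,
      cumulative_biomass = fit$asymptote /
        (1 + exp((fit$midpoint - xs) / fit$scale)))
    p <- p + ggplot2::geom_line(data = curve, colour = "red",
                                linewidth = 1)
  }
  p
}

#' Plot biomass against functional-group proportions
#'
#' One panel per functional group: cumulative biomass production (log10)
#' against the group's initial proportion, with median and quantile bands.
#'
#' @param results A `bq_scenario`.
#' @param q_low,q_high Quantile levels for the bands.
#' @return A ggplot object.
#' @export
plot_group_proportions <- function(results, q_low = 0.05, q_high = 0.95) {
  d <- tibble::as_tibble(results) |>
    tidyr::pivot_longer(dplyr::starts_with("prop_"), names_to = "group",
                        names_prefix = "prop_", values_to = "proportion")
  overall <- quantile_bands(results, q_low = q_low, q_high = q_high)
  ggplot2::ggplot(d, ggplot2::aes(.data$proportion,
                                  .data$cumulative_biomass)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_hline(yintercept = overall$median, linetype = "dashed",
                        linewidth = 1) +
    ggplot2::geom_hline(yintercept = c(overall$q_low, overall$q_high),
                        linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "Initial proportion of community",
                  y = "Cumulative biomass production (ng)") +
    ggplot2::theme_minimal()
}
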