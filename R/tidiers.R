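#' Tidy a simulation into a long trajectory table
#'
#' @param x A `bq_sim` from [run_simulation()] (run with
#'   `keep_trajectory = TRUE`).
#' @param ... Unused.
#' @return A tibble with one row per species per generation: `generation`,
#'   `species_id`, `strategy`, `group` (initial profile), `biomass`.
#' @export
tidy.bq_sim <- function(x, ...) {
  if (is.null(x$biomass)) {
    abort("Simulation was run with `keep_trajectory = FALSE`.",
          class = "bq_config_error")
  }
  n <- nrow(x$community0)
  tibble::tibble(
    generation = rep(0:x$generations, times = n),
    species_id = rep(x$community0$id, each = x$generations + 1),
    strategy = rep(x$community0$strategy, each = x$generations + 1),
    group = rep(x$community0$group, each = x$generations + 1),
    biomass = as.vector(x$biomass))
}

#' One-row summary of a simulation
#'
#' @inheritParams tidy.bq_sim
#' @return A one-row tibble: total cumulative production, final Shannon,
#'   survivors, mutation and extinction counts.
#' @export
glance.bq_sim <- function(x, ...) {
  tibble::tibble(cumulative_biomass = sum(x$cumulative_production),
                 shannon_final = x$shannon_final,
                 n_alive = sum(x$alive),
                 n_mutations = nrow(x$mutations),
                 n_extinctions = nrow(x$extinctions),
                 generations = x$generations,
                 environment = x$environment$mode)
}

#' Resource trajectories of a simulation
#'
#' @param x A `bq_sim` with trajectories.
#' @return A long tibble: `generation`, `resource` (C/G/A), `concentration`
#'   (mM).
#' @export
resource_trajectory <- function(x) {
  stopifnot(inherits(x, "bq_sim"))
  if (is.null(x$resources)) {
    abort("Simulation was run with `keep_trajectory = FALSE`.",
          class = "bq_config_error")
  }
  tibble::as_tibble(x$resources) |>
    dplyr::mutate(generation = 0:x$generations) |>
    tidyr::pivot_longer(c("C", "G", "A"), names_to = "resource",
                        values_to = "concentration")
}

#' @export
tidy.bq_scenario <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a Monte Carlo scenario
#'
#' @param x A `bq_scenario` from [run_scenario()].
#' @param ... Unused.
#' @return A one-row tibble with scenario metadata, median and mean
#'   cumulative biomass (plus the Monte Carlo standard error of the mean),
#'   median final Shannon, and the failed-replicate count.
#' @export
glance.bq_scenario <- function(x, ...) {
  ok <- is.na(x$error)
  b <- x$cumulative_biomass[ok]
  tibble::tibble(
    environment = attr(x, "environment"),
    mutation_rate = attr(x, "mutation_rate"),
    burden_mode = attr(x, "burden_mode"),
    n_replicates = nrow(x),
    n_failed = sum(!ok),
    median_biomass = median(b, na.rm = TRUE),
    mean_biomass = mean(b, na.rm = TRUE),
    se_biomass = sd(b, na.rm = TRUE) / sqrt(sum(is.finite(b))),
    median_log10_biomass = median(log10(b[b > 0]), na.rm = TRUE),
    median_shannon = median(x$shannon_final[ok], na.rm = TRUE))
}
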