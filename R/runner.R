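#' Simulation environments
#'
#' The two feeding regimes: `bulk_soil` receives a 2 mM cellulose pulse
#' every 100 generations (at generations 0, 100, 200, 300, 400 of a
#' 500-generation run) and no glucose or amino-acid inputs, so communities
#' must produce both; `rhizosphere` receives 2 mM glucose at every
#' generation, akin to root exudates, and amino acids are non-limiting
#' (the auxotroph limitation term is dropped from the equations). Pulses are
#' instantaneous additions at the generation boundary, before integration.
#'
#' @param mode `"bulk_soil"` or `"rhizosphere"`.
#' @param feed_amount Pulse size (mM).
#' @param feed_every Generations between pulses.
#' @return A list of class `bq_environment` with fields `mode`,
#'   `feed_resource`, `feed_amount`, `feed_every`.
#' @examples
#' bq_environment("bulk_soil")
#' @export
bq_environment <- function(mode = c("bulk_soil", "rhizosphere"),
                           feed_amount = 2,
                           feed_every = if (mode == "bulk_soil") 100 else 1) {
  if (is.list(mode) && inherits(mode, "bq_environment")) return(mode)
  mode <- match.arg(mode)
  structure(list(mode = mode,
                 feed_resource = if (mode == "bulk_soil") "C" else "G",
                 feed_amount = feed_amount,
                 feed_every = as.integer(feed_every)),
            class = "bq_environment")
}

# Pack community + globals into the padded parameter vector the compiled
# right-hand side expects (see src/bq_deriv.c for the layout).
BQ_MAXN <- 128L

build_parms <- function(community, alive, mode, params) {
  n <- nrow(community)
  if (n > BQ_MAXN) {
    abort(sprintf("At most %d species are supported.", BQ_MAXN),
          class = "bq_config_error")
  }
  block <- rbind(
    community$mu_max * params$eps_rel,
    community$Km_G,
    community$Km_A,
    community$Vmax_T * params$v_conv,
    community$Vmax_cel * params$v_conv,
    community$Km_cel,
    community$leak_max * params$v_conv,
    community$K_leak,
    community$m,
    as.double(community$cellulolytic),
    as.double(community$prototrophic),
    as.double(alive))
  c(n, as.double(mode == "rhizosphere"), params$G_death, params$y_CG,
    as.double(block), numeric(12L * (BQ_MAXN - n)))
}

integrate_generation <- function(y, parms, gen, rtol = 1e-6, atol = 1e-9) {
  out <- tryCatch(
    deSolve::ode(y = y, times = c(0, 1), func = "bq_deriv", parms = parms,
                 dllname = "bqsim", initfunc = "bq_init",
                 method = "lsoda", rtol = rtol, atol = atol),
    warning = function(w) {
      abort(sprintf("Solver failed at generation %d: %s", gen,
                    conditionMessage(w)),
            class = "bq_solver_error", state = y)
    },
    error = function(e) {
      abort(sprintf("Solver failed at generation %d: %s", gen,
                    conditionMessage(e)),
            class = "bq_solver_error", state = y)
    })
  y <- out[nrow(out), -1]
  pmax(y, 0)  # clamp solver overshoot near depletion
}

#' Advance a simulation by one generation
#'
#' Applies any scheduled feeding input at the generation boundary,
#' integrates the model over one generation of model time with the LSODA
#' stiff solver (rtol 1e-6, atol 1e-9), clamps negative overshoot, and
#' applies the extinction cutoff (biomass below `B_ext` is zeroed and the
#' species irreversibly flagged dead).
#'
#' @param state A [model_state()].
#' @param community A `bq_community` tibble.
#' @param environment A [bq_environment()] or mode string.
#' @param gen_index Zero-based generation boundary index: feeding occurs
#'   when `gen_index %% feed_every == 0`.
#' @param params A [bq_params()] object.
#' @return A list: `state` (the new [model_state()]) and `production`
#'   (per-species gross biomass produced during the generation, ng).
#' @export
step_generation <- function(state, community, environment, gen_index = 0,
                            params = bq_params()) {
  environment <- bq_environment(environment)
  parms <- build_parms(community, state$alive, environment$mode, params)
  y <- c(state$resources, state$biomass, numeric(length(state$biomass)))
  if (gen_index %% environment$feed_every == 0) {
    slot <- match(environment$feed_resource, c("C", "G", "A"))
    y[slot] <- y[slot] + environment$feed_amount
  }
  n <- nrow(community)
  if (any(state$alive)) {
    y <- integrate_generation(y, parms, gen_index)
  }
  biomass <- unname(y[4:(3 + n)])
  dead <- biomass < params$B_ext
  biomass[dead] <- 0
  list(state = model_state(y[1:3], biomass, state$alive & !dead),
       production = unname(y[(4 + n):(3 + 2 * n)]))
}

#' Run one community simulation
#'
#' Loops feeding, one-generation LSODA integration, extinction and
#' stochastic loss-of-function mutation for `generations` steps, tracking
#' biomass and resource trajectories, per-species cumulative gross biomass
#' production, the mutation and extinction logs, and the final Shannon
#' index. Deterministic given the community and `seed`.
#'
#' @param community A `bq_community` tibble (e.g. from
#'   [generate_community()]).
#' @param environment `"bulk_soil"`, `"rhizosphere"`, or a
#'   [bq_environment()].
#' @param mutation_rate Label or probability (see [mutation_rate()]).
#' @param generations Number of generations (default 500).
#' @param seed Optional seed for the mutation process.
#' @param params A [bq_params()] object.
#' @param keep_trajectory Set `FALSE` to skip storing per-generation
#'   matrices (used by the Monte Carlo driver).
#' @return An object of class `bq_sim`: a list with the initial and final
#'   rosters, `biomass` and `resources` trajectory matrices
#'   (generations+1 rows), per-species `cumulative_production` (ng),
#'   `shannon_final`, and tibbles `mutations` and `extinctions`.
#' @examples
#' bq <- new_community("copiotroph", TRUE, TRUE)
#' sim <- run_simulation(bq, "bulk_soil", generations = 50)
#' glance(sim)
#' @export
run_simulation <- function(community, environment = "bulk_soil",
                           mutation_rate = "null", generations = 500,
                           seed = NULL, params = bq_params(),
                           keep_trajectory = TRUE) {
  environment <- bq_environment(environment)
  rate <- mutation_rate(mutation_rate)
  n <- nrow(community)
  local_seed(seed)

  community0 <- community
  alive <- rep(TRUE, n)
  y <- c(c(C = 0, G = 0, A = 0), community$biomass0, numeric(n))
  parms <- build_parms(community, alive, environment$mode, params)
  slot <- match(environment$feed_resource, c("C", "G", "A"))

  if (keep_trajectory) {
    biomass_mat <- matrix(NA_real_, generations + 1, n)
    resource_mat <- matrix(NA_real_, generations + 1, 3,
                           dimnames = list(NULL, c("C", "G", "A")))
    biomass_mat[1, ] <- y[4:(3 + n)]
    resource_mat[1, ] <- y[1:3]
  }
  mutations <- list()
  extinct_at <- rep(NA_integer_, n)

  for (g in seq_len(generations)) {
    if ((g - 1) %% environment$feed_every == 0) {
      y[slot] <- y[slot] + environment$feed_amount
    }
    if (any(alive)) {
      y <- integrate_generation(y, parms, g)
      b <- y[4:(3 + n)]
      died <- alive & b < params$B_ext
      if (any(died)) {
        b[died] <- 0
        y[4:(3 + n)] <- b
        alive[died] <- FALSE
        extinct_at[died] <- g
        parms <- build_parms(community, alive, environment$mode, params)
      }
    }
    if (rate > 0 && any(alive)) {
      mut <- apply_mutations(community, rate, params, generation = g,
                             alive = alive)
      if (nrow(mut$events)) {
        community <- mut$community
        mutations[[length(mutations) + 1]] <- mut$events
        parms <- build_parms(community, alive, environment$mode, params)
      }
    }
    if (keep_trajectory) {
      biomass_mat[g + 1, ] <- y[4:(3 + n)]
      resource_mat[g + 1, ] <- y[1:3]
    }
  }

  final_b <- unname(y[4:(3 + n)])
  structure(list(
    community0 = community0,
    community = community,
    environment = environment,
    mutation_rate = rate,
    generations = generations,
    biomass = if (keep_trajectory) biomass_mat,
    resources = if (keep_trajectory) resource_mat,
    final_biomass = final_b,
    alive = alive,
    cumulative_production = unname(y[(4 + n):(3 + 2 * n)]),
    shannon_final = if (any(final_b > 0)) shannon_index(final_b) else NA_real_,
    mutations = if (length(mutations)) dplyr::bind_rows(mutations) else
      tibble::tibble(generation = integer(), species_id = integer(),
                     lost_function = character()),
    extinctions = tibble::tibble(
      species_id = community$id[!is.na(extinct_at)],
      generation = extinct_at[!is.na(extinct_at)])
  ), class = "bq_sim")
}

#' @export
print.bq_sim <- function(x, ...) {
  cat("<bq_sim>", x$environment$mode, "|", nrow(x$community), "species |",
      x$generations, "generations\n")
  cat("  cumulative production:", format(sum(x$cumulative_production),
                                         digits = 4), "ng |",
      sum(x$alive), "alive | final Shannon:",
      format(x$shannon_final, digits = 4), "\n")
  invisible(x)
}

# One-row summary used by the Monte Carlo driver.
summarise_simulation <- function(sim) {
  comm0 <- sim$community0
  cum <- sim$cumulative_production
  by_group <- vapply(functional_groups(),
                     function(g) sum(cum[comm0$group == g]), 0)
  by_strat <- vapply(life_strategies(),
                     function(s) sum(cum[comm0$strategy == s]), 0)
  props <- vapply(functional_groups(),
                  function(g) mean(comm0$group == g), 0)
  dplyr::bind_cols(
    tibble::tibble(cumulative_biomass = sum(cum),
                   shannon_final = sim$shannon_final,
                   n_alive = sum(sim$alive),
                   n_mutations = nrow(sim$mutations)),
    tibble::as_tibble(as.list(setNames(by_group,
                                       paste0("cum_", names(by_group))))),
    tibble::as_tibble(as.list(setNames(by_strat,
                                       paste0("cum_", names(by_strat))))),
    tibble::as_tibble(as.list(setNames(props,
                                       paste0("prop_", names(props)))))
  )
}

#' Run a Monte Carlo scenario
#'
#' One cell of the environment-by-mutation-rate grid: draws a completely new
#' random community for every replicate (from seeds derived deterministically
#' from the root seed and replicate index, so replicates are independent,
#' order-insensitive and reproducible) and runs a full simulation for each.
#'
#' @param environment `"bulk_soil"` or `"rhizosphere"` (or a
#'   [bq_environment()]).
#' @param mutation_rate Label (`"null"`, `"low"`, `"medium"`, `"high"`) or
#'   probability.
#' @param n_replicates Number of Monte Carlo replicates (1000 in the full
#'   design; smaller values give the same per-replicate results for the
#'   shared seeds).
#' @param generations Generations per simulation (default 500).
#' @param seed Root seed for the scenario.
#' @param n_species Species per community (default 20).
#' @param params A [bq_params()] object (use
#'   `bq_params("swapped")` for the swapped-burden sensitivity mode).
#' @return A `bq_scenario` tibble with one row per replicate: seeds, total
#'   and per-group/per-strategy cumulative biomass production (ng), final
#'   Shannon index, survivor and mutation counts, and initial
#'   functional-group proportions. Scenario metadata is stored in
#'   attributes (`environment`, `mutation_rate`, `seed`, `generations`,
#'   `burden_mode`).
#' @examples
#' sc <- run_scenario("bulk_soil", "null", n_replicates = 3, seed = 1,
#'                    generations = 100)
#' glance(sc)
#' @export
run_scenario <- function(environment = "bulk_soil", mutation_rate = "null",
                         n_replicates = 1000, generations = 500, seed = 1,
                         n_species = 20, params = bq_params()) {
  stopifnot(n_replicates >= 1)
  environment <- bq_environment(environment)
  rate_label <- if (is.character(mutation_rate)) mutation_rate else
    as.character(mutation_rate)
  rate <- mutation_rate(mutation_rate)

  rows <- purrr::map(seq_len(n_replicates), function(i) {
    cseed <- derive_seed(seed, i, stream = 1L)
    mseed <- derive_seed(seed, i, stream = 2L)
    res <- tryCatch({
      comm <- generate_community(n_species, params, seed = cseed)
      sim <- run_simulation(comm, environment, rate,
                            generations = generations, seed = mseed,
                            params = params, keep_trajectory = FALSE)
      dplyr::bind_cols(
        tibble::tibble(replicate = i, seed_community = cseed,
                       seed_mutation = mseed, error = NA_character_),
        summarise_simulation(sim))
    }, error = function(e) {
      tibble::tibble(replicate = i, seed_community = cseed,
                     seed_mutation = mseed, error = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "environment") <- environment$mode
  attr(out, "mutation_rate") <- rate
  attr(out, "mutation_rate_label") <- rate_label
  attr(out, "seed") <- seed
  attr(out, "generations") <- generations
  attr(out, "n_species") <- n_species
  attr(out, "burden_mode") <- params$burden_mode
  class(out) <- c("bq_scenario", class(out))
  out
}

#' Run the full scenario grid
#'
#' All environment-by-mutation-rate combinations (the full design is 2
#' environments x 4 rates x 1000 replicates = 8000 simulations).
#'
#' @inheritParams run_scenario
#' @param environments,mutation_rates Vectors of labels defining the grid.
#' @return A tibble binding all scenario tables, with `environment` and
#'   `mutation_rate` columns.
#' @export
run_grid <- function(environments = c("bulk_soil", "rhizosphere"),
                     mutation_rates = c("null", "low", "medium", "high"),
                     n_replicates = 1000, generations = 500, seed = 1,
                     n_species = 20, params = bq_params()) {
  grid <- tidyr::expand_grid(environment = environments,
                             mutation_rate = mutation_rates)
  purrr::pmap(grid, function(environment, mutation_rate) {
    sc <- run_scenario(environment, mutation_rate,
                       n_replicates = n_replicates,
                       generations = generations,
                       seed = derive_seed(seed,
                                          match(environment, environments),
                                          match(mutation_rate,
                                                mutation_rates) + 10L),
                       n_species = n_species, params = params)
    dplyr::mutate(tibble::as_tibble(sc), environment = environment,
                  mutation_rate = mutation_rate, .before = 1)
  }) |> dplyr::bind_rows()
}
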