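# Shared fixtures, built in code.

# One representative of every profile, deterministic order.
all_profiles_community <- function(params = bq_params()) {
  grid <- expand.grid(strategy = life_strategies(),
                      cellulolytic = c(TRUE, FALSE),
                      prototrophic = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  new_community(grid$strategy, grid$cellulolytic, grid$prototrophic, params)
}

# Classic fixed-step RK4 on the reference R derivative; the independent
# integration oracle for the compiled LSODA path.
rk4_generation <- function(state, community, environment, params,
                           dt = 1e-4) {
  pack <- function(s) c(s$resources, s$biomass)
  unpack <- function(y, s) model_state(y[1:3], pmax(y[-(1:3)], 0), s$alive)
  f <- function(s) {
    d <- derivative(0, s, community, environment, params)
    c(d$resources, d$biomass)
  }
  y <- pack(state)
  s <- state
  n <- round(1 / dt)
  for (i in seq_len(n)) {
    k1 <- f(unpack(y, s))
    k2 <- f(unpack(y + dt / 2 * k1, s))
    k3 <- f(unpack(y + dt / 2 * k2, s))
    k4 <- f(unpack(y + dt * k3, s))
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  unpack(y, s)
}

# Scenario cache so acceptance-style checks reuse Monte Carlo runs across
# test blocks instead of re-simulating.
.scenario_cache <- new.env(parent = emptyenv())
cached_scenario <- function(environment, rate, n, seed = 42,
                            params = bq_params()) {
  key <- paste(environment, rate, n, seed, params$burden_mode, sep = "|")
  if (is.null(.scenario_cache[[key]])) {
    .scenario_cache[[key]] <- run_scenario(environment, rate,
                                           n_replicates = n, seed = seed,
                                           params = params)
  }
  .scenario_cache[[key]]
}
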