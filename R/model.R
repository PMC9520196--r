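#' Model state
#'
#' Bundles the three shared resource pools with the per-species biomass
#' vector and alive flags. Dead species have zero biomass and identically
#' zero derivatives.
#'
#' @param resources Named numeric vector `c(C =, G =, A =)` in mM
#'   (cellulose in glucose-equivalents).
#' @param biomass Per-species biomass vector (ng, >= 0).
#' @param alive Logical vector; defaults to `biomass > 0`.
#' @return A list of class `bq_state`.
#' @examples
#' model_state(c(C = 2, G = 0, A = 0), biomass = rep(1, 20))
#' @export
model_state <- function(resources = c(C = 0, G = 0, A = 0),
                        biomass, alive = biomass > 0) {
  resources <- resources[c("C", "G", "A")]
  if (anyNA(resources) || any(resources < 0)) {
    abort("Resources must be named C/G/A and non-negative.",
          class = "bq_parameter_error")
  }
  stopifnot(all(biomass >= 0), length(alive) == length(biomass))
  if (any(!alive & biomass > 0)) {
    abort("Dead species must have zero biomass.",
          class = "bq_parameter_error")
  }
  structure(list(resources = resources, biomass = as.double(biomass),
                 alive = alive), class = "bq_state")
}

#' Community cellulase flux
#'
#' Total rate of cellulose-to-glucose conversion (mM/generation) by alive
#' cellulolytic species: the biomass-weighted sum of their Michaelis-Menten
#' cellulase rates, converted to pool units through `v_conv`.
#'
#' @param state A [model_state()].
#' @param community A `bq_community` tibble.
#' @param params A [bq_params()] object (supplies `v_conv`).
#' @return Cellulose degradation rate (mM/generation, >= 0).
#' @export
cellulase_flux <- function(state, community, params = bq_params()) {
  C <- state$resources[["C"]]
  on <- state$alive & community$cellulolytic
  sum(michaelis_menten_rate(community$Vmax_cel[on], C, community$Km_cel[on]) *
        state$biomass[on]) * params$v_conv
}

#' Specific transporter uptake rate
#'
#' Michaelis-Menten uptake of glucose or amino acids by one species, per ng
#' of its biomass (mmol/ng/generation). Amino-acid uptake is only defined
#' for auxotrophs in the bulk-soil equation set: prototrophs synthesise
#' their own, so requesting `"A"` for a prototroph is a contract error.
#'
#' @param species_index Row of the species in `community`.
#' @param resource `"G"` or `"A"`.
#' @param state A [model_state()].
#' @param community A `bq_community` tibble.
#' @return Specific uptake rate (mmol per ng per generation).
#' @export
uptake_flux <- function(species_index, resource = c("G", "A"), state,
                        community) {
  resource <- match.arg(resource)
  i <- species_index
  if (resource == "A" && community$prototrophic[i]) {
    abort("Amino-acid uptake is only defined for auxotrophs.",
          class = "bq_contract_error")
  }
  Km <- if (resource == "G") community$Km_G[i] else community$Km_A[i]
  michaelis_menten_rate(community$Vmax_T[i], state$resources[[resource]], Km)
}

#' Amino-acid leakage flux of one prototroph
#'
#' Monod-type leakage tied to the glucose-driven activity of the producer:
#' `leak_max * B * G / (K_leak + G) * v_conv` (mM/generation). Auxotrophs
#' leak nothing, and inactive cells (no glucose) leak nothing.
#'
#' @inheritParams uptake_flux
#' @param params A [bq_params()] object.
#' @return Rate of amino-acid production (mM/generation).
#' @export
amino_leakage_flux <- function(species_index, state, community,
                               params = bq_params()) {
  i <- species_index
  if (!community$prototrophic[i] || !state$alive[i]) return(0)
  G <- state$resources[["G"]]
  community$leak_max[i] * state$biomass[i] *
    monod_fraction(G, community$K_leak[i]) * params$v_conv
}

#' Net specific growth rate of one species
#'
#' `mu_max * eps_rel * f_lim * act - m`, where the limitation term `f_lim`
#' is the glucose Monod fraction for prototrophs and the Liebig minimum of
#' the glucose and amino-acid fractions for auxotrophs (glucose only in the
#' rhizosphere, where amino acids are non-limiting), and `act` is the
#' dormancy switch: when glucose falls below the death threshold `G_death`
#' the growth term is suppressed and the species decays at its maintenance
#' burden, `-m` (the switch is a steep smooth gate, Hill exponent 6, so the
#' suppression is numerically exact a short distance below the threshold).
#'
#' @inheritParams amino_leakage_flux
#' @param environment `"bulk_soil"` or `"rhizosphere"`.
#' @return Net specific growth rate (1/generation).
#' @export
growth_rate <- function(species_index, state, community,
                        environment = c("bulk_soil", "rhizosphere"),
                        params = bq_params()) {
  environment <- match.arg(environment)
  i <- species_index
  G <- state$resources[["G"]]
  f_lim <- monod_fraction(G, community$Km_G[i])
  if (!community$prototrophic[i] && environment == "bulk_soil") {
    f_lim <- min(f_lim, monod_fraction(state$resources[["A"]],
                                       community$Km_A[i]))
  }
  activity_switch(G, params$G_death) * community$mu_max[i] * params$eps_rel *
    f_lim - community$m[i]
}

# Smooth dormancy gate around the glucose death threshold (Hill exponent
# 6): ~1 above G_death, ~0 below, solver-friendly in between.
activity_switch <- function(G, G_death) {
  ifelse(G > 0, 1 / (1 + (G_death / G)^6), 0)
}

#' Model derivative (reference R implementation)
#'
#' Assembles the full right-hand side: `dC/dt` (cellulase degradation),
#' `dG/dt` (glucose release minus transporter drawdown), `dA/dt` (prototroph
#' leakage minus auxotroph uptake; not evaluated in the rhizosphere, where
#' amino acids are non-limiting), `dB_i/dt` (net growth) and `dP_i/dt` (the
#' gross production term integrated into cumulative biomass production).
#' This pure-R version defines the model; simulations run the identical
#' compiled version through [deSolve::ode()] for speed.
#'
#' @param t Time (unused; the within-generation system is autonomous).
#' @param state A [model_state()].
#' @param community A `bq_community` tibble.
#' @param environment `"bulk_soil"` or `"rhizosphere"`.
#' @param params A [bq_params()] object.
#' @return A list with `resources` (named dC/dG/dA), `biomass` (dB) and
#'   `production` (dP, gross growth, always >= 0).
#' @export
derivative <- function(t, state, community,
                       environment = c("bulk_soil", "rhizosphere"),
                       params = bq_params()) {
  environment <- match.arg(environment)
  rhizo <- environment == "rhizosphere"
  G <- state$resources[["G"]]
  A <- state$resources[["A"]]
  n <- nrow(community)

  cel <- cellulase_flux(state, community, params)

  # Below the death threshold cells go dormant: growth, transport and
  # leakage stop together (extracellular cellulase keeps working). `act`
  # is the smooth dormancy switch.
  act <- activity_switch(G, params$G_death)

  fG <- monod_fraction(G, community$Km_G)
  drawdown_G <- act *
    sum((community$Vmax_T * fG * state$biomass)[state$alive]) * params$v_conv

  dA <- 0
  f_lim <- fG
  if (!rhizo) {
    fA <- monod_fraction(A, community$Km_A)
    aux <- !community$prototrophic
    f_lim[aux] <- pmin(fG[aux], fA[aux])
    leak <- sum(vapply(seq_len(n), amino_leakage_flux, 0,
                       state = state, community = community,
                       params = params))
    drawdown_A <- sum((community$Vmax_T * fA * state$biomass)[
      state$alive & aux]) * params$v_conv
    dA <- act * (leak - drawdown_A)
  }

  gross <- act * community$mu_max * params$eps_rel * f_lim
  gross[!state$alive] <- 0
  dB <- (gross - community$m) * state$biomass
  dB[!state$alive] <- 0
  dP <- gross * state$biomass

  list(resources = c(C = -cel, G = params$y_CG * cel - drawdown_G, A = dA),
       biomass = dB, production = dP)
}
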