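params <- bq_params()

test_that("cellulase flux follows Michaelis-Menten in cellulose", {
  comm <- all_profiles_community()
  st <- model_state(c(C = 2, G = 0.05, A = 0.01),
                    biomass = rep(100, nrow(comm)))
  # no producers: kill all cellulolytic species
  b <- ifelse(comm$cellulolytic, 0, 100)
  st0 <- model_state(c(C = 2, G = 0.05, A = 0.01), b)
  expect_equal(cellulase_flux(st0, comm, params), 0)
  # zero substrate
  stC0 <- model_state(c(C = 0, G = 0.05, A = 0.01), rep(100, nrow(comm)))
  expect_equal(cellulase_flux(stC0, comm, params), 0)
  # one producer, C at its half-saturation: flux = 0.5 * Vmax_cel * B * v_conv
  one <- new_community("copiotroph", TRUE, TRUE,
                       bq_params(Km_cel = 2))
  st1 <- model_state(c(C = 2, G = 0, A = 0), biomass = 100)
  expect_equal(cellulase_flux(st1, one, bq_params(Km_cel = 2)),
               0.5 * one$Vmax_cel * 100 * params$v_conv)
})

test_that("transporter uptake honours affinity and the prototroph contract", {
  comm <- all_profiles_community()
  st <- model_state(c(C = 0, G = 0, A = 0.01), rep(1, nrow(comm)))
  for (i in seq_len(nrow(comm))) {
    expect_equal(uptake_flux(i, "G", st, comm), 0)  # no glucose
  }
  # half-saturation identity
  i_cop <- which(comm$strategy == "copiotroph")[1]
  st2 <- model_state(c(C = 0, G = comm$Km_G[i_cop], A = 0),
                     rep(1, nrow(comm)))
  expect_equal(uptake_flux(i_cop, "G", st2, comm), comm$Vmax_T[i_cop] / 2)
  # at equal Vmax_T and low substrate the high-affinity strategy wins
  pair <- new_community(c("copiotroph", "oligotroph"), TRUE, TRUE)
  pair$Vmax_T <- 1e-10
  stlow <- model_state(c(C = 0, G = 0.003, A = 0), c(1, 1))
  expect_gt(uptake_flux(2, "G", stlow, pair),
            uptake_flux(1, "G", stlow, pair))
  # amino-acid uptake is an auxotroph-only contract
  i_aux <- which(!comm$prototrophic)[1]
  i_pro <- which(comm$prototrophic)[1]
  expect_gt(uptake_flux(i_aux, "A", st, comm), 0)
  expect_error(uptake_flux(i_pro, "A", st, comm),
               class = "bq_contract_error")
})

test_that("amino-acid leakage is prototroph-only and glucose-driven", {
  comm <- all_profiles_community()
  i_aux <- which(!comm$prototrophic)[1]
  i_pro <- which(comm$prototrophic)[1]
  st <- model_state(c(C = 0, G = comm$K_leak[i_pro], A = 0),
                    rep(50, nrow(comm)))
  expect_equal(amino_leakage_flux(i_aux, st, comm, params), 0)
  stG0 <- model_state(c(C = 0, G = 0, A = 0), rep(50, nrow(comm)))
  expect_equal(amino_leakage_flux(i_pro, stG0, comm, params), 0)
  # G at K_leak: half-maximal specific leakage
  expect_equal(amino_leakage_flux(i_pro, st, comm, params),
               0.5 * comm$leak_max[i_pro] * 50 * params$v_conv)
})

test_that("growth saturates, dies below threshold, and obeys Liebig", {
  one <- new_community("copiotroph", TRUE, TRUE)
  # saturation limit: net -> mu_max * eps_rel - m
  st_hi <- model_state(c(C = 0, G = 500, A = 500), 1)
  expect_equal(growth_rate(1, st_hi, one, "bulk_soil", params),
               one$mu_max * params$eps_rel - one$m, tolerance = 1e-2)
  # death phase: far enough below 10 uM glucose, net = -m
  st_lo <- model_state(c(C = 0, G = 0.002, A = 500), 1)
  expect_equal(growth_rate(1, st_lo, one, "bulk_soil", params),
               -one$m, tolerance = 1e-4)
  # auxotroph with no amino acids: Liebig minimum drives net to -m exactly
  aux <- new_community("copiotroph", TRUE, FALSE)
  st_a0 <- model_state(c(C = 0, G = 500, A = 0), 1)
  expect_equal(growth_rate(1, st_a0, aux, "bulk_soil", params), -aux$m)
  # ... but amino acids are non-limiting in the rhizosphere
  expect_gt(growth_rate(1, st_a0, aux, "rhizosphere", params), 0)
})

test_that("the derivative of an all-dead community is zero", {
  comm <- all_profiles_community()
  st <- model_state(c(C = 1, G = 0.5, A = 0.1),
                    biomass = rep(0, nrow(comm)),
                    alive = rep(FALSE, nrow(comm)))
  d <- derivative(0, st, comm, "bulk_soil", params)
  expect_equal(unname(d$resources), c(0, 0, 0))
  expect_equal(d$biomass, rep(0, nrow(comm)))
  expect_equal(d$production, rep(0, nrow(comm)))
})

test_that("glucose gain equals the cellulose yield when uptake is absent", {
  p <- bq_params()
  one <- new_community("copiotroph", TRUE, TRUE, p)
  one$Vmax_T <- 1e-30   # negligible drawdown
  one$leak_max <- 1e-30
  st <- model_state(c(C = 1.5, G = 0.05, A = 0), 200)
  d <- derivative(0, st, one, "bulk_soil", p)
  expect_lt(d$resources[["C"]], 0)
  expect_equal(d$resources[["G"]], -p$y_CG * d$resources[["C"]],
               tolerance = 1e-10)
})

test_that("glucose production never exceeds the cellulose ledger", {
  # with consumers active, dG/dt <= y_CG * (-dC/dt)
  comm <- all_profiles_community()
  set.seed(31)
  for (i in 1:20) {
    st <- model_state(c(C = runif(1, 0, 3), G = runif(1, 0, 0.2),
                        A = runif(1, 0, 0.05)),
                      biomass = runif(nrow(comm), 0, 300))
    d <- derivative(0, st, comm, "bulk_soil", params)
    expect_lte(d$resources[["G"]],
               params$y_CG * (-d$resources[["C"]]) + 1e-12)
  }
})

test_that("stiff solver matches a fixed-step RK4 oracle on 2 species", {
  p <- bq_params()
  duo <- new_community(c("copiotroph", "oligotroph"), c(TRUE, FALSE),
                       c(TRUE, FALSE), p)
  st <- model_state(c(C = 1, G = 0.05, A = 0.02), c(50, 50))
  lsoda_out <- step_generation(st, duo, bq_environment("bulk_soil",
                                                       feed_amount = 0),
                               gen_index = 1, params = p)$state
  rk4_out <- rk4_generation(st, duo, "bulk_soil", p, dt = 1e-4)
  expect_equal(lsoda_out$resources, rk4_out$resources, tolerance = 1e-4)
  expect_equal(lsoda_out$biomass, rk4_out$biomass, tolerance = 1e-4)
})

test_that("carbon accounting bounds production by glucose turnover", {
  # per-species structural bound: eps * Vmax_T >= mu_max * eps_rel, so
  # production can never outrun eps * uptake ...
  set.seed(12)
  for (i in 1:50) {
    comm <- generate_community(seed = i)
    expect_true(all(comm$eps * comm$Vmax_T >=
                      comm$mu_max * bq_params()$eps_rel - 1e-12))
  }
  # ... and at the whole-community level, cumulative production is bounded
  # by the best yield times all glucose that ever entered the pool
  comm <- generate_community(seed = 4)
  sim <- run_simulation(comm, "bulk_soil", generations = 200, seed = 1)
  fed_C <- 2 * 2  # pulses at generations 0 and 100
  glucose_mM <- bq_params()$y_CG * (fed_C - sim$resources[201, "C"])
  cap <- max(comm$eps) / bq_params()$v_conv * glucose_mM
  expect_lte(sum(sim$cumulative_production), cap * (1 + 1e-6))
})

test_that("state invariants are enforced", {
  expect_error(model_state(c(C = -1, G = 0, A = 0), 1),
               class = "bq_parameter_error")
  expect_error(model_state(c(C = 0, G = 0, A = 0), biomass = 2,
                           alive = FALSE),
               class = "bq_parameter_error")
  # no state variable goes below zero across a whole simulation
  sim <- run_simulation(generate_community(seed = 2), "bulk_soil",
                        generations = 150, seed = 3)
  expect_true(all(sim$resources >= 0))
  expect_true(all(sim$biomass >= 0))
})
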