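test_that("Shannon index matches hand values and its bounds", {
  expect_equal(shannon_index(rep(1, 20)), log(20))
  expect_equal(shannon_index(c(0, 7, 0)), 0)
  expect_equal(shannon_index(c(0.7, 0.3)),
               -(0.7 * log(0.7) + 0.3 * log(0.3)))
  expect_equal(shannon_index(c(0.7, 0.3)), 0.6109, tolerance = 1e-4)
  expect_error(shannon_index(numeric(0)), class = "bq_diversity_error")
  expect_error(shannon_index(c(0, 0)), class = "bq_diversity_error")
  expect_error(shannon_index(c(1, -1)), class = "bq_parameter_error")
  set.seed(1)
  for (i in 1:30) {
    b <- runif(sample(2:30, 1)) * sample(c(1, 100), 1)
    H <- shannon_index(b)
    expect_gte(H, 0)
    expect_lte(H, log(sum(b > 0)) + 1e-12)
  }
})

test_that("Shannon agrees with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(2)
  for (i in 1:20) {
    b <- runif(20, 0, 10)
    expect_equal(shannon_index(b),
                 unname(vegan::diversity(matrix(b, 1), index = "shannon")),
                 tolerance = 1e-8)
  }
})

test_that("logistic fit recovers noiseless and noisy truths", {
  x <- seq(0.2, 3.5, length.out = 120)
  y <- 5000 / (1 + exp((2.1 - x) / 0.25))
  fit <- fit_logistic(data.frame(s = x, b = y), s, b)
  expect_equal(fit$asymptote, 5000, tolerance = 1e-4)
  expect_equal(fit$midpoint, 2.1, tolerance = 1e-4)
  expect_equal(fit$scale, 0.25, tolerance = 1e-4)
  expect_gt(fit$r_squared, 0.9999)
  expect_equal(fit$saturation, 2.1 + log(0.95 / 0.05) * 0.25,
               tolerance = 1e-4)
  # constant response: rejected (no spread)
  expect_error(fit_logistic(data.frame(s = x, b = rep(1, 120)), s, b),
               class = "bq_fit_error")
  # noisy recovery within a loose simulation tolerance
  set.seed(5)
  yn <- y + rnorm(120, 0, 150)
  fitn <- fit_logistic(data.frame(s = x, b = yn), s, b)
  expect_equal(fitn$asymptote, 5000, tolerance = 0.05)
  expect_equal(fitn$midpoint, 2.1, tolerance = 0.05)
  expect_gt(fitn$r_squared, 0.9)
  expect_lt(fitn$p_value, 1e-10)
  g <- glance(fitn)
  expect_equal(g$r.squared, fitn$r_squared)
  expect_equal(nrow(tidy(fitn)), 3)
})

test_that("Welch's t matches the textbook formula", {
  welch_oracle <- function(x, y) {
    sx <- var(x) / length(x); sy <- var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(sx + sy)
    df <- (sx + sy)^2 / (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
    c(t = t, df = df, p = 2 * pt(-abs(t), df))
  }
  x <- c(2.1, 2.5, 2.3); y <- c(1.1, 1.4, 1.2)
  got <- welch_t_test(x, y)
  want <- welch_oracle(x, y)
  expect_equal(got$statistic, unname(want["t"]), tolerance = 1e-8)
  expect_equal(got$df, unname(want["df"]), tolerance = 1e-8)
  expect_equal(got$p_value, unname(want["p"]), tolerance = 1e-8)
  expect_equal(got$statistic, 7.341, tolerance = 0.001)
  set.seed(3)
  for (i in 1:25) {
    a <- rnorm(sample(5:40, 1)); b <- rnorm(sample(5:40, 1), sd = 2)
    g <- welch_t_test(a, b); w <- welch_oracle(a, b)
    expect_equal(g$statistic, unname(w["t"]), tolerance = 1e-8)
    expect_equal(g$p_value, unname(w["p"]), tolerance = 1e-8)
  }
  # identical samples: t = 0, p = 1; separated samples: p -> 0
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_lt(welch_t_test(c(1, 2, 3), c(1, 2, 3) + 1e4)$p_value, 1e-6)
  expect_error(welch_t_test(1, c(1, 2)), class = "bq_stat_error")
})

test_that("Kruskal-Wallis matches hand ranks and is rank-invariant", {
  # perfect separation of {1,2},{3,4},{5,6}: by hand, ranks 1..6 give
  # H = 12/42 * (9/2 + 49/2 + 121/2) - 21 = 32/7
  got <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(got$statistic, 32 / 7, tolerance = 1e-8)
  expect_equal(got$df, 2)
  # identical values: degenerate, H = 0, p = 1
  flat <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # invariance under strictly monotone transforms
  set.seed(8)
  g <- list(runif(10), runif(12, 0.2), runif(9, 0.5))
  h1 <- kruskal_wallis(g)
  h2 <- kruskal_wallis(lapply(g, function(v) exp(3 * v) + 1))
  expect_equal(h1$statistic, h2$statistic, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1, 2)), class = "bq_stat_error")
})

test_that("quantile bands are ordered and match order statistics", {
  const <- tibble::tibble(cumulative_biomass = rep(3, 50), replicate = 1:50)
  b <- quantile_bands(const)
  expect_equal(c(b$q_low, b$median, b$q_high), c(3, 3, 3))
  set.seed(9)
  unif <- tibble::tibble(cumulative_biomass = runif(1e5), replicate = 1)
  bu <- quantile_bands(unif)
  expect_equal(c(bu$q_low, bu$median, bu$q_high), c(0.05, 0.5, 0.95),
               tolerance = 0.01)
  expect_true(bu$q_low <= bu$median && bu$median <= bu$q_high)
})

test_that("group regressions recover exact and null slopes", {
  set.seed(10)
  prop <- sample(0:20, 300, replace = TRUE) / 20
  exact <- tibble::tibble(prop_black_queen = prop,
                          cumulative_biomass = 10^(2 * prop))
  g <- suppressWarnings(group_proportion_regression(exact, "black_queen"))
  expect_equal(g$beta, 2, tolerance = 1e-10)
  expect_equal(g$r_squared, 1, tolerance = 1e-10)
  # shuffled labels: no relationship
  null <- tibble::tibble(prop_cheater = sample(prop),
                         cumulative_biomass = 10^(2 * prop))
  gn <- group_proportion_regression(null, "cheater")
  expect_lt(abs(gn$beta), 0.3)
  expect_lt(gn$r_squared, 0.05)
  # zero variance in the proportion is an error
  degenerate <- tibble::tibble(prop_cheater = rep(0.25, 50),
                               cumulative_biomass = runif(50))
  expect_error(group_proportion_regression(degenerate, "cheater"),
               class = "bq_fit_error")
})

test_that("R-squared is invariant to affine rescaling of the response", {
  set.seed(11)
  d <- tibble::tibble(prop_cheater = sample(0:20, 200, TRUE) / 20)
  d$cumulative_biomass <- 10^(0.8 * d$prop_cheater + rnorm(200, 0, 0.2))
  r1 <- group_proportion_regression(d, "cheater")$r_squared
  d2 <- d
  d2$cumulative_biomass <- d$cumulative_biomass^3 * 10  # affine on log10
  r2 <- group_proportion_regression(d2, "cheater")$r_squared
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("strategy split partitions the community total", {
  sc <- cached_scenario("bulk_soil", "null", 8)
  sp <- strategy_split(sc)
  expect_equal(sp$copiotroph + sp$oligotroph, sp$total, tolerance = 1e-9)
  # an all-copiotroph community has a zero oligotroph share
  comm <- new_community(rep("copiotroph", 6), TRUE, TRUE)
  sim <- run_simulation(comm, "bulk_soil", generations = 100)
  expect_equal(sum(sim$cumulative_production[comm$strategy == "oligotroph"]),
               0)
})
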