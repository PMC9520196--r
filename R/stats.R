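#' Shannon diversity index
#'
#' `H = -sum p_i log p_i` over the strictly positive entries of a biomass
#' (or abundance) vector, natural log by default. Zero-biomass species are
#' excluded; an all-zero vector has undefined diversity and raises an error.
#'
#' @param biomass Non-negative numeric vector.
#' @param base Logarithm base (default `exp(1)`).
#' @return The Shannon index (dimensionless, in `[0, log(n)]`).
#' @examples
#' shannon_index(rep(1, 20))  # log(20) = 2.9957...
#' shannon_index(c(0.7, 0.3))
#' @export
shannon_index <- function(biomass, base = exp(1)) {
  if (any(!is.finite(biomass)) || any(biomass < 0)) {
    abort("Biomass must be finite and non-negative.",
          class = "bq_parameter_error")
  }
  p <- biomass[biomass > 0]
  if (!length(p)) {
    abort("Shannon diversity is undefined for an all-zero community.",
          class = "bq_diversity_error")
  }
  p <- p / sum(p)
  -sum(p * log(p, base = base))
}

#' Logistic fit of biomass on Shannon diversity
#'
#' Fits the three-parameter logistic
#' `y = Asym / (1 + exp((xmid - x) / scal))` of cumulative biomass on the
#' Shannon index by nonlinear least squares with the standard self-starting
#' initialisation ([stats::SSlogis()]), mirroring the
#' biodiversity-ecosystem-function analysis of the null-mutation scenarios.
#' Also reports `R^2 = 1 - SSE/SST`, an F-test p-value against the constant
#' model, and the saturation threshold `xmid + k * scal` beyond which extra
#' diversity yields diminishing returns (with the default
#' `k = log(0.05 / 0.95)` sign convention below, the curve has reached 95%
#' of its asymptote).
#'
#' @param data A data frame (e.g. a `bq_scenario`).
#' @param shannon,biomass Column names (tidy-eval) of the predictor and
#'   response; defaults match `bq_scenario` columns.
#' @param k Multiplier defining the saturation threshold `xmid + k * scal`
#'   (default `log(0.95/0.05)`, the 95%-of-asymptote point).
#' @return A `bq_logistic` object with elements `fit` (the `nls` object),
#'   `asymptote`, `midpoint`, `scale`, `r_squared`, `p_value`,
#'   `saturation`, `n`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' x <- seq(0.5, 3, length.out = 100)
#' y <- 5000 / (1 + exp((2 - x) / 0.2))
#' fit <- fit_logistic(data.frame(s = x, b = y), s, b)
#' glance(fit)
#' @export
fit_logistic <- function(data, shannon = shannon_final,
                         biomass = cumulative_biomass,
                         k = log(0.95 / 0.05)) {
  x <- dplyr::pull(data, {{ shannon }})
  y <- dplyr::pull(data, {{ biomass }})
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 10 || sd(x) == 0 || sd(y) == 0) {
    abort("Need >= 10 points with positive spread in both variables.",
          class = "bq_fit_error")
  }
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    nls(y ~ SSlogis(x, Asym, xmid, scal), data = df,
        control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # Levenberg-Marquardt fallback over a small start grid: saturating
    # scatter with little curvature often defeats the self-start.
    starts <- expand.grid(Asym = max(y) * c(1.05, 1.5),
                          xmid = unname(quantile(x, c(0.25, 0.5))),
                          scal = sd(x) * c(0.25, 1))
    for (i in seq_len(nrow(starts))) {
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ Asym / (1 + exp((xmid - x) / scal)),
                          data = df, start = as.list(starts[i, ]),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit)) {
    abort("Logistic fit did not converge.", class = "bq_fit_error")
  }
  est <- coef(fit)
  sse <- sum(stats::resid(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  # F test of the 3-parameter logistic against the intercept-only model
  df1 <- 2
  df2 <- length(y) - 3
  f <- ((sst - sse) / df1) / (sse / df2)
  structure(list(fit = fit,
                 asymptote = unname(est["Asym"]),
                 midpoint = unname(est["xmid"]),
                 scale = unname(est["scal"]),
                 r_squared = r2,
                 p_value = pf(f, df1, df2, lower.tail = FALSE),
                 saturation = unname(est["xmid"] + k * est["scal"]),
                 n = length(y)),
            class = "bq_logistic")
}

#' @export
print.bq_logistic <- function(x, ...) {
  cat("<bq_logistic> y = Asym / (1 + exp((xmid - x)/scal))\n")
  cat(sprintf("  Asym %.4g | xmid %.4g | scal %.4g | R2 %.3f | p %.3g\n",
              x$asymptote, x$midpoint, x$scale, x$r_squared, x$p_value))
  cat(sprintf("  saturation threshold (Shannon): %.3f | n = %d\n",
              x$saturation, x$n))
  invisible(x)
}

#' @export
tidy.bq_logistic <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std.error = s[, 2], statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.bq_logistic <- function(x, ...) {
  tibble::tibble(asymptote = x$asymptote, midpoint = x$midpoint,
                 scale = x$scale, r.squared = x$r_squared,
                 p.value = x$p_value, saturation = x$saturation, nobs = x$n)
}

#' Functional-group proportion regression
#'
#' Ordinary least squares of log10 total cumulative biomass on a functional
#' group's initial proportion of the community (count / community size),
#' computed on a null-mutation scenario table where composition is fixed.
#' The slope (beta) measures how much an extra share of the group raises
#' community production.
#'
#' @param results A `bq_scenario` (or compatible data frame with
#'   `cumulative_biomass` and `prop_<group>` columns).
#' @param group One of [functional_groups()].
#' @return A one-row tibble of class `bq_group_regression`: `group`, `beta`,
#'   `r_squared`, `p_value`, `n`.
#' @export
group_proportion_regression <- function(results, group) {
  group <- match.arg(group, functional_groups())
  col <- paste0("prop_", group)
  if (!col %in% names(results)) {
    abort(sprintf("Column `%s` not found in `results`.", col),
          class = "bq_config_error")
  }
  d <- data.frame(x = results[[col]],
                  y = log10(results$cumulative_biomass))
  d <- d[is.finite(d$x) & is.finite(d$y), ]
  if (nrow(d) < 3 || var(d$x) == 0) {
    abort("Zero variance in the group proportion (or too few rows).",
          class = "bq_fit_error")
  }
  fit <- lm(y ~ x, data = d)
  s <- summary(fit)
  out <- tibble::tibble(group = group,
                        beta = unname(coef(fit)[2]),
                        r_squared = s$r.squared,
                        p_value = s$coefficients[2, 4],
                        n = nrow(d))
  class(out) <- c("bq_group_regression", class(out))
  out
}

#' Welch's unequal-variance t test
#'
#' Two-sided Welch t test (Welch-Satterthwaite degrees of freedom), as used
#' to compare community properties between environments. Thin tidy wrapper
#' around [stats::t.test()].
#'
#' @param x,y Numeric samples (each of length >= 2, non-degenerate).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `estimate_x`,
#'   `estimate_y`.
#' @examples
#' welch_t_test(c(2.1, 2.5, 2.3), c(1.1, 1.4, 1.2))
#' @export
welch_t_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2 || (var(x) == 0 && var(y) == 0)) {
    abort("Welch's t test needs two non-degenerate samples of size >= 2.",
          class = "bq_stat_error")
  }
  ht <- t.test(x, y, var.equal = FALSE)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 estimate_x = mean(x), estimate_y = mean(y))
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based H statistic with tie correction and chi-square p-value on
#' k - 1 degrees of freedom, used for biomass across the mutation-rate
#' gradient. Thin tidy wrapper around [stats::kruskal.test()]; a fully
#' degenerate input (all values identical) returns `H = 0`, `p = 1`.
#'
#' @param groups A list of numeric vectors, or a data frame given with
#'   `value` and `group` columns via `values`/`labels`.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(values) < 3) {
    abort("Kruskal-Wallis needs a total sample size of >= 3.",
          class = "bq_stat_error")
  }
  if (length(unique(values)) == 1) {
    return(tibble::tibble(statistic = 0, df = length(groups) - 1,
                          p_value = 1, n = length(values)))
  }
  ht <- kruskal.test(values, labels)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value, n = length(values))
}

#' Quantile bands of biomass across group proportions
#'
#' Median and lower/upper quantiles (default 5% and 95%) of cumulative
#' biomass production, overall and within bins of a functional group's
#' initial proportion. Empty bins are reported as missing rather than
#' interpolated.
#'
#' @param results A `bq_scenario` (or compatible data frame).
#' @param group Optional functional-group label; if supplied, bands are
#'   computed within proportion bins for that group, otherwise a single
#'   overall row is returned.
#' @param q_low,q_high Quantile levels.
#' @param binwidth Width of proportion bins (default 0.05, one species in
#'   20).
#' @return A tibble with `proportion` (bin midpoint, `NA` for the overall
#'   row), `n`, `q_low`, `median`, `q_high`.
#' @export
quantile_bands <- function(results, group = NULL, q_low = 0.05,
                           q_high = 0.95, binwidth = 0.05) {
  stopifnot(q_low <= 0.5, q_high >= 0.5)
  bands <- function(v) {
    q <- quantile(v, c(q_low, 0.5, q_high), names = FALSE, na.rm = TRUE)
    tibble::tibble(n = sum(is.finite(v)), q_low = q[1], median = q[2],
                   q_high = q[3])
  }
  if (is.null(group)) {
    return(dplyr::bind_cols(tibble::tibble(proportion = NA_real_),
                            bands(results$cumulative_biomass)))
  }
  group <- match.arg(group, functional_groups())
  col <- paste0("prop_", group)
  results |>
    dplyr::mutate(proportion = floor(.data[[col]] / binwidth) * binwidth +
                    binwidth / 2) |>
    dplyr::group_by(.data$proportion) |>
    dplyr::reframe(bands(.data$cumulative_biomass))
}

#' Cumulative biomass split by life strategy
#'
#' Per-replicate cumulative biomass production of copiotrophic versus
#' oligotrophic species; the two totals partition the community total.
#'
#' @param results A `bq_scenario` (its per-strategy columns are produced by
#'   the scenario driver).
#' @return A tibble with `replicate`, `copiotroph`, `oligotroph`, `total`.
#' @export
strategy_split <- function(results) {
  tibble::tibble(replicate = results$replicate,
                 copiotroph = results$cum_copiotroph,
                 oligotroph = results$cum_oligotroph,
                 total = results$cumulative_biomass)
}
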