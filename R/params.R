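#' Default model parameter set
#'
#' Assembles the kinetic and bioenergetic parameter table used by
#' [generate_community()] and the simulator. Values are the package defaults:
#' they satisfy every structural constraint of the model (copiotrophs have a
#' 10-fold higher maximum growth rate, oligotroph transporters a higher
#' substrate affinity, maintenance burdens strictly ordered
#' black queen > cellulolytic auxotroph > non-cellulolytic prototroph >
#' cheater with a small oligotroph increment) and were calibrated once so
#' that bulk-soil communities produce cumulative biomass on the
#' \eqn{10^3}--\eqn{10^4} ng scale (see the methods vignette for the
#' calibration rationale).
#'
#' Units: biomass in ng, resource pools in mM, time in generations. Specific
#' rates (`Vmax_T`, `Vmax_cel`, `leak_max`) are in mmol per ng biomass per
#' generation and act on the shared pools through the volume conversion
#' constant `v_conv` (1/L; pool change in mM = flux in mmol times `v_conv`).
#'
#' @param burden_mode `"default"` keeps the oligotroph maintenance increment
#'   (+`olig_m_increment`); `"swapped"` moves the increment to copiotrophs
#'   instead, for the sensitivity analysis in which copiotrophs carry the
#'   greater burden.
#' @param ... Named overrides for any element of the returned list
#'   (e.g. `eps_rel = 0.4`, `G_death = 0.02`).
#'
#' @return An object of class `bq_params`: a named list with
#'   \describe{
#'     \item{strategies}{tibble of per-strategy kinetics: `mu_max` (1/gen),
#'       `Km_G`, `Km_A` (mM), `Vmax_T` (mmol/ng/gen).}
#'     \item{maintenance}{tibble of per-group copiotroph burdens (1/gen).}
#'     \item{olig_m_increment}{extra burden carried by the strategy with
#'       high-affinity (ATP-dependent) transporters.}
#'     \item{burden_mode}{`"default"` or `"swapped"`.}
#'     \item{eps_rel}{dimensionless growth-efficiency factor in (0, 1].}
#'     \item{Vmax_cel, Km_cel}{cellulase kinetics (mmol/ng/gen; mM).}
#'     \item{leak_max, K_leak}{amino-acid leakage kinetics (mmol/ng/gen; mM).}
#'     \item{v_conv}{volume conversion, 1/L (default 1e7, i.e. 0.1 uL of
#'       aggregate pore water).}
#'     \item{y_CG}{glucose yield per cellulose degraded (glucose-equivalents).}
#'     \item{G_death}{glucose death threshold (mM); growth is suppressed
#'       below it.}
#'     \item{B_ext}{extinction cutoff (ng).}
#'     \item{B_init}{initial biomass per species (ng).}
#'   }
#' @examples
#' p <- bq_params()
#' p$strategies
#' bq_params("swapped")$burden_mode
#' @export
bq_params <- function(burden_mode = c("default", "swapped"), ...) {
  burden_mode <- match.arg(burden_mode)
  p <- list(
    strategies = tibble::tibble(
      strategy = c("copiotroph", "oligotroph"),
      mu_max   = c(3.0, 0.3),
      Km_G     = c(0.5, 0.005),
      Km_A     = c(0.5, 0.02),
      Vmax_T   = c(1e-10, 5e-12)
    ),
    maintenance = tibble::tibble(
      group = c("black_queen", "cellulolytic_auxotroph",
                "non_cellulolytic_prototroph", "cheater"),
      m     = c(0.030, 0.026, 0.022, 0.018)
    ),
    olig_m_increment = 0.003,
    burden_mode = burden_mode,
    eps_rel  = 0.5,
    Vmax_cel = 2.0e-11,
    Km_cel   = 1.0,
    leak_max = 1.0e-12,
    K_leak   = 0.01,
    v_conv   = 1e7,
    y_CG     = 1.0,
    G_death  = 0.01,
    B_ext    = 1e-3,
    B_init   = 8
  )
  p <- modifyList(p, list(...))
  validate_bq_params(structure(p, class = "bq_params"))
}

validate_bq_params <- function(p) {
  stopifnot(inherits(p, "bq_params"))
  kin <- c(p$strategies$mu_max, p$strategies$Km_G, p$strategies$Km_A,
           p$strategies$Vmax_T, p$Vmax_cel, p$Km_cel, p$leak_max, p$K_leak,
           p$v_conv, p$G_death, p$B_ext, p$B_init)
  if (any(!is.finite(kin)) || any(kin <= 0)) {
    abort("All kinetic/affinity parameters must be strictly positive.",
          class = "bq_parameter_error")
  }
  if (p$eps_rel <= 0 || p$eps_rel > 1) {
    abort("`eps_rel` must lie in (0, 1].", class = "bq_parameter_error")
  }
  mu <- p$strategies$mu_max[match(c("copiotroph", "oligotroph"),
                                  p$strategies$strategy)]
  if (!isTRUE(all.equal(mu[1] / mu[2], 10))) {
    abort("Copiotroph mu_max must be 10x the oligotroph mu_max.",
          class = "bq_parameter_error")
  }
  km <- p$strategies$Km_G[match(c("copiotroph", "oligotroph"),
                                p$strategies$strategy)]
  if (!(km[2] < km[1])) {
    abort("Oligotroph transporter Km must be below the copiotroph Km.",
          class = "bq_parameter_error")
  }
  if (is.unsorted(rev(p$maintenance$m), strictly = TRUE)) {
    abort(paste0("Maintenance burdens must be strictly ordered black queen > ",
                 "cellulolytic auxotroph > non-cellulolytic prototroph > ",
                 "cheater."),
          class = "bq_parameter_error")
  }
  if (p$olig_m_increment <= 0) {
    abort("`olig_m_increment` must be positive.", class = "bq_parameter_error")
  }
  p
}

#' @export
print.bq_params <- function(x, ...) {
  cat("<bq_params> consumer-resource model parameters\n")
  cat("  burden_mode:", x$burden_mode,
      " eps_rel:", x$eps_rel,
      " G_death:", x$G_death, "mM\n")
  print(x$strategies)
  print(dplyr::mutate(
    x$maintenance,
    m_oligotroph = .data$m +
      if (x$burden_mode == "default") x$olig_m_increment else 0,
    m_copiotroph = .data$m +
      if (x$burden_mode == "swapped") x$olig_m_increment else 0
  ))
  invisible(x)
}

#' Maintenance burden of a trait profile
#'
#' The specific maintenance cost (1/generation) a species pays for the
#' functional machinery it carries. Burdens are strictly ordered
#' black queen > cellulolytic auxotroph > non-cellulolytic prototroph >
#' cheater (cellulase is assumed costlier than amino-acid production), and
#' the strategy with energy-dependent high-affinity transporters (oligotrophs
#' by default, copiotrophs in the swapped sensitivity mode) pays a small
#' additional increment.
#'
#' @param strategy Character vector, `"copiotroph"` or `"oligotroph"`.
#' @param cellulolytic,prototrophic Logical vectors of trait flags.
#' @param params A [bq_params()] object.
#' @return Numeric vector of burdens (1/generation).
#' @examples
#' maintenance_burden("copiotroph", TRUE, TRUE)   # black queen
#' maintenance_burden("oligotroph", FALSE, FALSE) # oligotrophic cheater
#' @export
maintenance_burden <- function(strategy, cellulolytic, prototrophic,
                               params = bq_params()) {
  group <- classify_functional_group(cellulolytic, prototrophic)
  base <- params$maintenance$m[match(group, params$maintenance$group)]
  inc_strategy <- if (params$burden_mode == "swapped") "copiotroph"
                  else "oligotroph"
  base + ifelse(strategy == inc_strategy, params$olig_m_increment, 0)
}

# ng biomass per mmol glucose: couples the growth term to transporter
# drawdown so gross production never exceeds eps * glucose uptake.
species_eps <- function(mu_max, eps_rel, Vmax_T) {
  mu_max * eps_rel / Vmax_T
}
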