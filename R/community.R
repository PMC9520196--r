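#' Classify a trait profile into a functional group
#'
#' The two public-good traits map to exactly four functional groups:
#' cellulolytic prototrophs are black queens (they carry both costly,
#' shareable functions), non-cellulolytic auxotrophs are cheaters (they carry
#' neither and depend entirely on others), and the two single-trait profiles
#' sit in between.
#'
#' @param cellulolytic,prototrophic Logical vectors (recycled to a common
#'   length).
#' @return Character vector with values `"black_queen"`,
#'   `"cellulolytic_auxotroph"`, `"non_cellulolytic_prototroph"`, `"cheater"`.
#' @examples
#' classify_functional_group(TRUE, TRUE)   # black queen
#' classify_functional_group(FALSE, FALSE) # cheater
#' @export
classify_functional_group <- function(cellulolytic, prototrophic) {
  stopifnot(is.logical(cellulolytic), is.logical(prototrophic))
  dplyr::case_when(
    cellulolytic & prototrophic   ~ "black_queen",
    cellulolytic & !prototrophic  ~ "cellulolytic_auxotroph",
    !cellulolytic & prototrophic  ~ "non_cellulolytic_prototroph",
    .default = "cheater"
  )
}

#' Functional group and strategy labels
#'
#' @return Character vectors of the four functional-group labels (ordered by
#'   decreasing maintenance burden) and the two life-strategy labels.
#' @export
functional_groups <- function() {
  c("black_queen", "cellulolytic_auxotroph",
    "non_cellulolytic_prototroph", "cheater")
}

#' @rdname functional_groups
#' @export
life_strategies <- function() {
  c("copiotroph", "oligotroph")
}

#' Generate a random community
#'
#' Draws `n` species independently: functional group uniform over the four
#' trait combinations and life strategy uniform over
#' copiotroph/oligotroph, giving eight equiprobable profiles. Kinetic
#' parameters are assigned from the per-strategy parameter table, the
#' maintenance burden from the trait profile, and every species starts at the
#' same initial biomass so that final diversity is purely outcome-driven.
#'
#' @param n Number of species (default 20).
#' @param params A [bq_params()] object.
#' @param seed Optional integer seed; the same seed always yields the same
#'   roster (drawn from a locally scoped RNG state).
#' @return A `bq_community` tibble with one row per species: identity
#'   (`id`, `strategy`, `cellulolytic`, `prototrophic`, `group`), kinetics
#'   (`mu_max`, `Km_G`, `Km_A`, `Vmax_T`, `eps`, `Vmax_cel`, `Km_cel`,
#'   `leak_max`, `K_leak`), the maintenance burden `m`, and the starting
#'   biomass `biomass0` (ng).
#' @examples
#' comm <- generate_community(seed = 1)
#' dplyr::count(comm, group, strategy)
#' @export
generate_community <- function(n = 20, params = bq_params(), seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  local_seed(seed)
  cellulolytic <- sample(c(TRUE, FALSE), n, replace = TRUE)
  prototrophic <- sample(c(TRUE, FALSE), n, replace = TRUE)
  strategy <- sample(life_strategies(), n, replace = TRUE)
  new_community(strategy, cellulolytic, prototrophic, params)
}

#' Assemble a community from explicit trait profiles
#'
#' Deterministic companion to [generate_community()] for building specific
#' rosters (e.g. a lone copiotrophic black queen, or an all-cheater
#' community).
#'
#' @param strategy Character vector of life strategies.
#' @param cellulolytic,prototrophic Logical trait vectors.
#' @param params A [bq_params()] object.
#' @inherit generate_community return
#' @examples
#' new_community("copiotroph", TRUE, TRUE)  # one copiotrophic black queen
#' @export
new_community <- function(strategy, cellulolytic, prototrophic,
                          params = bq_params()) {
  n <- max(length(strategy), length(cellulolytic), length(prototrophic))
  strategy <- rep_len(strategy, n)
  cellulolytic <- rep_len(cellulolytic, n)
  prototrophic <- rep_len(prototrophic, n)
  if (!all(strategy %in% life_strategies())) {
    abort("`strategy` must be 'copiotroph' or 'oligotroph'.",
          class = "bq_parameter_error")
  }
  idx <- match(strategy, params$strategies$strategy)
  comm <- tibble::tibble(
    id = seq_len(n),
    strategy = strategy,
    cellulolytic = cellulolytic,
    prototrophic = prototrophic,
    group = classify_functional_group(cellulolytic, prototrophic),
    mu_max = params$strategies$mu_max[idx],
    Km_G = params$strategies$Km_G[idx],
    Km_A = params$strategies$Km_A[idx],
    Vmax_T = params$strategies$Vmax_T[idx],
    eps = species_eps(params$strategies$mu_max[idx], params$eps_rel,
                      params$strategies$Vmax_T[idx]),
    Vmax_cel = params$Vmax_cel,
    Km_cel = params$Km_cel,
    leak_max = params$leak_max,
    K_leak = params$K_leak,
    m = maintenance_burden(strategy, cellulolytic, prototrophic, params),
    biomass0 = params$B_init
  )
  class(comm) <- c("bq_community", class(comm))
  comm
}

#' Mutation-rate labels
#'
#' Maps the four named mutation regimes to their per-species per-generation
#' loss-of-function probabilities: null = 0, low = 4.5e-4, medium = 4.5e-3
#' (the observed *E. coli* per-generation rate the medium regime emulates),
#' high = 4.5e-2.
#'
#' @param rate A label (`"null"`, `"low"`, `"medium"`, `"high"`) or a numeric
#'   probability in `[0, 1]`, possibly vectorised.
#' @return Numeric vector of probabilities.
#' @examples
#' mutation_rate("medium") # 4.5e-3
#' @export
mutation_rate <- function(rate) {
  rates <- c(null = 0, low = 4.5e-4, medium = 4.5e-3, high = 4.5e-2)
  if (is.character(rate)) {
    if (!all(rate %in% names(rates))) {
      abort("Mutation-rate labels must be one of null/low/medium/high.",
            class = "bq_config_error")
    }
    return(unname(rates[rate]))
  }
  stopifnot(is.numeric(rate), all(rate >= 0 & rate <= 1))
  rate
}

#' Apply one generation of loss-of-function mutation
#'
#' Each alive species independently suffers a loss-of-function mutation with
#' probability `rate`. A mutating species loses one function it still
#' possesses (chosen uniformly when both cellulase and amino-acid production
#' remain); functions are only ever lost, never regained, and every loss
#' strictly lowers the species' maintenance burden. Cheaters have nothing
#' left to lose and generate no events.
#'
#' @param community A `bq_community` tibble.
#' @param rate Mutation probability per species per generation (label or
#'   numeric, see [mutation_rate()]).
#' @param params The [bq_params()] object used to recompute burdens.
#' @param generation Generation index recorded in the event log.
#' @param alive Logical vector marking which species can still mutate
#'   (default: all).
#' @return A list with elements `community` (traits and burdens updated) and
#'   `events` (tibble with columns `generation`, `species_id`,
#'   `lost_function`).
#' @examples
#' comm <- generate_community(seed = 1)
#' set.seed(2)
#' apply_mutations(comm, "high")$events
#' @export
apply_mutations <- function(community, rate, params = bq_params(),
                            generation = NA_integer_,
                            alive = rep(TRUE, nrow(community))) {
  rate <- mutation_rate(rate)
  stopifnot(length(rate) == 1)
  n <- nrow(community)
  events <- tibble::tibble(generation = integer(), species_id = integer(),
                           lost_function = character())
  if (rate > 0) {
    hit <- stats::runif(n) < rate
    can <- community$cellulolytic | community$prototrophic
    for (i in which(hit & can & alive)) {
      lose <- c("cellulase", "amino_acid_production")[
        c(community$cellulolytic[i], community$prototrophic[i])]
      lost <- if (length(lose) == 2) sample(lose, 1) else lose
      if (lost == "cellulase") community$cellulolytic[i] <- FALSE
      else community$prototrophic[i] <- FALSE
      events <- dplyr::bind_rows(events, tibble::tibble(
        generation = as.integer(generation), species_id = community$id[i],
        lost_function = lost))
    }
    if (any(hit & can & alive)) {
      community$group <- classify_functional_group(community$cellulolytic,
                                                   community$prototrophic)
      community$m <- maintenance_burden(community$strategy,
                                        community$cellulolytic,
                                        community$prototrophic, params)
    }
  }
  list(community = community, events = events)
}

# Locally scope the global RNG: set `seed` for the calling frame and restore
# the previous .Random.seed when that frame exits.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  withr::defer(
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv()),
    envir = env)
  set.seed(seed)
  invisible()
}

#' Derive a reproducible sub-seed
#'
#' Deterministically mixes a root seed with a replicate index and stream id
#' so that Monte Carlo replicates are independently reproducible (and
#' parallel execution is bit-identical to serial). Uses a Lehmer-style
#' multiplicative congruential mix modulo 2^31 - 1.
#'
#' @param root Root integer seed.
#' @param index Replicate index (>= 0), possibly vectorised.
#' @param stream Stream id separating e.g. community generation from the
#'   mutation process.
#' @return Integer seed(s) in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, index, stream = 0L) {
  m <- 2147483647
  x <- (abs(as.double(root)) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + as.double(index) * 16807 + as.double(stream) * 69621) %% m
  x <- (x * 48271) %% m
  x <- (x * 48271) %% m
  as.integer(x %% (m - 2)) + 1L
}
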