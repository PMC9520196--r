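#' Load and validate a scenario configuration
#'
#' Reads a YAML configuration describing the scenario grid and any parameter
#' overrides, validates it against the schema, and fills defaults (an empty
#' file yields the full design: 20 species, 500 generations, 1000
#' replicates, 2 environments x 4 mutation rates). Unknown keys are
#' rejected by name; mutation-rate labels resolve through
#' [mutation_rate()].
#'
#' @param path Path to a YAML file.
#' @return A list of class `bq_config`: `seed`, `generations`,
#'   `n_replicates`, `n_species`, `environments`, `mutation_rates`,
#'   `burden_mode`, and a validated [bq_params()] object in `params`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "bq_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("seed", "generations", "n_replicates", "n_species",
             "environments", "mutation_rates", "burden_mode", "params")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    abort(sprintf("Unknown config key(s): %s", paste(bad, collapse = ", ")),
          class = "bq_config_error")
  }
  cfg <- modifyList(list(seed = 1L, generations = 500L,
                         n_replicates = 1000L, n_species = 20L,
                         environments = c("bulk_soil", "rhizosphere"),
                         mutation_rates = c("null", "low", "medium", "high"),
                         burden_mode = "default"),
                    raw[setdiff(names(raw), "params")])
  if (!all(cfg$environments %in% c("bulk_soil", "rhizosphere"))) {
    abort("`environments` must be bulk_soil and/or rhizosphere.",
          class = "bq_config_error")
  }
  mutation_rate(cfg$mutation_rates)  # validates labels/values
  for (key in c("seed", "generations", "n_replicates", "n_species")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      abort(sprintf("Config key `%s` must be a positive integer.", key),
            class = "bq_config_error")
    }
    cfg[[key]] <- as.integer(v)
  }
  overrides <- raw$params %||% list()
  param_keys <- names(bq_params())
  bad <- setdiff(names(overrides), param_keys)
  if (length(bad)) {
    abort(sprintf("Unknown parameter key(s): %s",
                  paste(bad, collapse = ", ")),
          class = "bq_config_error")
  }
  for (tab in c("strategies", "maintenance")) {
    if (!is.null(overrides[[tab]])) {
      overrides[[tab]] <- tibble::as_tibble(
        as.data.frame(lapply(overrides[[tab]], unlist)))
    }
  }
  cfg$params <- do.call(bq_params,
                        c(list(burden_mode = cfg$burden_mode), overrides))
  structure(cfg, class = "bq_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable checksum of the parameter table (via its canonical JSON form).
param_checksum <- function(params) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(params), tmp, digits = NA, auto_unbox = TRUE)
  unname(tools::md5sum(tmp))
}

#' Build a run manifest
#'
#' A JSON-serialisable record from which every output can be reproduced:
#' configuration snapshot, root seed, parameter-table checksum, per-scenario
#' metadata, package version and timestamp.
#'
#' @param results A `bq_scenario` or a list of them.
#' @param params The [bq_params()] object used.
#' @return A list ready for [jsonlite::write_json()].
#' @export
run_manifest <- function(results, params = bq_params()) {
  scens <- if (inherits(results, "bq_scenario")) list(results) else results
  list(
    package = "bqsim",
    version = as.character(packageVersion("bqsim")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    parameter_checksum = param_checksum(params),
    burden_mode = params$burden_mode,
    scenarios = lapply(scens, function(s) list(
      environment = attr(s, "environment"),
      mutation_rate = attr(s, "mutation_rate"),
      mutation_rate_label = attr(s, "mutation_rate_label"),
      seed = attr(s, "seed"),
      generations = attr(s, "generations"),
      n_species = attr(s, "n_species"),
      n_replicates = nrow(s)))
  )
}

#' Write scenario results to disk
#'
#' Tidy CSVs (one row per replicate, C-locale numeric formatting) plus a
#' JSON run manifest.
#'
#' @param results A `bq_scenario` or named list of them.
#' @param out_dir Output directory (created if needed).
#' @param params The [bq_params()] used, recorded in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, out_dir, params = bq_params()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scens <- if (inherits(results, "bq_scenario"))
    setNames(list(results),
             paste(attr(results, "environment"),
                   attr(results, "mutation_rate_label"), sep = "_"))
  else results
  paths <- character()
  for (nm in names(scens)) {
    p <- file.path(out_dir, paste0("scenario_", nm, ".csv"))
    write.csv(tibble::as_tibble(scens[[nm]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(run_manifest(unname(scens), params), mp,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, mp))
}

#' Read a scenario result CSV back
#'
#' Round-trip companion to [write_results()].
#'
#' @param path CSV path written by [write_results()].
#' @return A tibble (without the scenario attributes, which live in the
#'   manifest).
#' @export
read_scenario <- function(path) {
  out <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if ("error" %in% names(out)) out$error <- as.character(out$error)
  out
}
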