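# Serialisation of qs_config to/from plain nested lists (YAML on disk).
# Schema is versioned; readers reject configs written under a different
# schema, and unknown keys are an error so silent typos cannot change a
# run.

qs_schema_version <- 1L

config_to_list <- function(config) {
  stopifnot(inherits(config, "qs_config"))
  mx <- config$mixing
  mu <- config$mutation
  pa <- config$payoff
  list(
    schema_version = qs_schema_version,
    pool_size = config$pool_size,
    generations = config$generations,
    summary_window = config$summary_window,
    cheat_injection = config$cheat_injection,
    init = config$init,
    mixing = list(lambda = mx$lambda, fixed_g = mx$fixed_g, law = mx$law),
    mutation = list(prob = as.list(mu$prob), sd_frac = as.list(mu$sd_frac),
                    freeze = as.list(mu$freeze),
                    bounds = unclass(mu$bounds)),
    payoff = list(baseline = pa$baseline, b_coop = pa$b_coop,
                  c_coop = pa$c_coop, c_sig = pa$c_sig,
                  n_th = pa$n_th, mode = pa$mode),
    dynamics = list(k = config$dynamics$k),
    env = list(u = config$env$u, m = config$env$m,
               noise_sd = config$env$noise_sd),
    grid = list(low = config$grid[1],
                high = config$grid[length(config$grid)],
                count = length(config$grid))
  )
}

check_keys <- function(lst, allowed, where) {
  extra <- setdiff(names(lst), allowed)
  if (length(extra)) {
    abort(sprintf("unknown config key(s) in %s: %s",
                  where, paste(extra, collapse = ", ")))
  }
}

config_from_list <- function(lst) {
  check_keys(lst, c("schema_version", "pool_size", "generations",
                    "summary_window", "cheat_injection", "init", "mixing",
                    "mutation", "payoff", "dynamics", "env", "grid"),
             "top level")
  sv <- lst$schema_version %||% NA_integer_
  if (!identical(as.integer(sv), qs_schema_version)) {
    abort(sprintf("config schema version %s does not match supported version %d",
                  sv, qs_schema_version))
  }
  check_keys(lst$mixing %||% list(), c("lambda", "fixed_g", "law"), "mixing")
  check_keys(lst$mutation %||% list(), c("prob", "sd_frac", "freeze", "bounds"),
             "mutation")
  check_keys(lst$payoff %||% list(),
             c("baseline", "b_coop", "c_coop", "c_sig", "n_th", "mode"),
             "payoff")
  check_keys(lst$dynamics %||% list(), "k", "dynamics")
  check_keys(lst$env %||% list(), c("u", "m", "noise_sd"), "env")
  check_keys(lst$grid %||% list(), c("low", "high", "count"), "grid")

  bounds <- do.call(trait_bounds, lst$mutation$bounds %||% list())
  mut_args <- lst$mutation %||% list()
  mutation <- mutation_model(
    prob = unlist(mut_args$prob %||% 0.1),
    sd_frac = unlist(mut_args$sd_frac %||% 0.02),
    freeze = as.character(unlist(mut_args$freeze %||% character())),
    bounds = bounds)
  mixing <- do.call(mixing_config, lst$mixing %||% list())
  payoff <- do.call(payoff_params, lst$payoff %||% list())
  dynamics <- do.call(dynamics_params, lst$dynamics %||% list())
  env <- do.call(signal_env, lst$env %||% list())
  grid_spec <- lst$grid %||% list()
  grid <- do.call(build_density_grid, grid_spec)

  qs_config(
    pool_size = lst$pool_size %||% 500,
    generations = lst$generations %||% 300,
    mixing = mixing, mutation = mutation, payoff = payoff,
    dynamics = dynamics, env = env, grid = grid,
    init = lst$init %||% list(p = 1e-8, s_th = 1, r = 0),
    cheat_injection = lst$cheat_injection %||% 0,
    summary_window = lst$summary_window %||% 50
  )
}

#' Write a simulation configuration to YAML
#'
#' @param config a [qs_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qs_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' The file must carry the current schema version; unknown keys and
#' out-of-range values are rejected with the offending field named.
#'
#' @param path YAML file written by [write_qs_config()] (or by hand in
#'   the same structure).
#' @return A validated [qs_config()].
#' @export
read_qs_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  config_from_list(yaml::read_yaml(path))
}

#' Write per-generation records to CSV
#'
#' One row per generation, RFC-4180 quoting, schema-versioned via an
#' accompanying column.
#'
#' @param sim a `qs_sim`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_qs_records <- function(sim, path) {
  rec <- dplyr::mutate(sim$records, schema_version = qs_schema_version,
                       seed = sim$seed)
  readr::write_csv(rec, path)
  invisible(path)
}

#' Read per-generation records from CSV
#'
#' @param path CSV written by [write_qs_records()].
#' @return Records tibble (without the schema bookkeeping columns).
#' @export
read_qs_records <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE)
  if (!"schema_version" %in% names(rec) ||
      !all(rec$schema_version == qs_schema_version)) {
    abort("records file schema version mismatch")
  }
  dplyr::select(rec, -"schema_version")
}
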