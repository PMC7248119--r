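#' Simulation configuration
#'
#' Bundles everything one evolutionary run needs. The full-scale study
#' conditions are 5,000 individuals for 5,000 generations with summaries
#' over the last 50 generations; the reduced-scale preset (see
#' [qs_preset()]) uses pool 500 for 300 generations.
#'
#' @param pool_size number of individuals in the propagule pool.
#' @param generations number of non-overlapping generations.
#' @param mixing a [mixing_config()].
#' @param mutation a [mutation_model()].
#' @param payoff a [payoff_params()].
#' @param dynamics a [dynamics_params()].
#' @param env a [signal_env()] (density field unused; densities come from
#'   the grid).
#' @param grid density grid, from [build_density_grid()].
#' @param init named list of founding trait values `p`, `s_th`, `r`; the
#'   initial pool is this genotype replicated `pool_size` times. The
#'   default is an initially identical, cooperating but mis-tuned
#'   genotype (it switches on far below the critical density), so
#'   selection immediately sees a coordination gradient; a
#'   never-cooperating start sits in a fitness valley many mutational
#'   SDs wide and does not adapt on observable timescales.
#' @param cheat_injection fraction of offspring replaced by constitutive
#'   cheats each generation (default 0); the count is
#'   `round(fraction * pool_size)` and replacement keeps the pool size
#'   fixed.
#' @param summary_window number of final generations that evolved-mean
#'   summaries average over (default 50).
#' @return A list of class `qs_config`.
#' @export
qs_config <- function(pool_size = 500, generations = 300,
                      mixing = mixing_config(fixed_g = 1),
                      mutation = mutation_model(),
                      payoff = payoff_params(),
                      dynamics = dynamics_params(),
                      env = signal_env(),
                      grid = build_density_grid(),
                      init = list(p = 1e-8, s_th = 1, r = 0),
                      cheat_injection = 0,
                      summary_window = 50) {
  check_num(pool_size, "pool_size", lower = 2)
  check_num(generations, "generations", lower = 1)
  check_num(cheat_injection, "cheat_injection", lower = 0, upper = 1)
  check_num(summary_window, "summary_window", lower = 1)
  stopifnot(inherits(mixing, "qs_mixing"), inherits(mutation, "qs_mutation"),
            inherits(payoff, "qs_payoff"), inherits(dynamics, "qs_dynamics"),
            inherits(env, "qs_env"))
  # the feedback ratio is an evolving trait only in auto mode
  if (payoff$mode != "qs_auto" && !("r" %in% mutation$freeze)) {
    mutation$freeze <- union(mutation$freeze, "r")
  }
  structure(list(
    pool_size = as.integer(pool_size),
    generations = as.integer(generations),
    mixing = mixing, mutation = mutation, payoff = payoff,
    dynamics = dynamics, env = env, grid = grid,
    init = init, cheat_injection = cheat_injection,
    summary_window = as.integer(summary_window)
  ), class = "qs_config")
}

record_row <- function(gen, pool, ev) {
  tibble::tibble(
    generation = gen,
    mean_p = mean(pool$p), sd_p = sd(pool$p),
    mean_s_th = mean(pool$s_th), sd_s_th = sd(pool$s_th),
    mean_r = mean(pool$r), sd_r = sd(pool$r),
    mean_payoff = mean(ev$fitness),
    frac_on = mean(ev$investment),
    diversity = dplyr::n_distinct(pool$lineage),
    cheat_frac = mean(pool$immutable)
  )
}

#' Advance one generation
#'
#' One turn of the loop: found groups, evaluate every founder across the
#' density grid, select `pool_size` offspring by multinomial sampling
#' with weights `max(payoff - min(payoff), eps)`, mutate them, and
#' replace a `cheat_injection` fraction with constitutive cheats.
#'
#' @param pool current `qs_pool` tibble (size = `config$pool_size`).
#' @param config a [qs_config()].
#' @param gen generation index to stamp on the record.
#' @param next_lineage first free lineage id.
#' @return A list with `pool` (offspring), `record` (one-row tibble),
#'   `next_lineage`, and `eval` (list with parent `gid`, `fitness`,
#'   `investment`, `parent_idx` of each offspring, for selection
#'   analyses).
#' @export
run_generation <- function(pool, config, gen = 1L,
                           next_lineage = max(pool$lineage) + 1L) {
  n <- config$pool_size
  stopifnot(nrow(pool) == n)
  gid <- found_groups(pool, config$mixing)
  ev <- eval_engine(pool, gid, config$grid, config$env,
                    config$dynamics, config$payoff)
  w <- ev$fitness - min(ev$fitness)
  rng <- max(w)
  if (rng == 0) {
    w <- rep(1, n)                     # pure drift
  } else {
    w <- w + 1e-9 * rng
  }
  idx <- sample.int(n, n, replace = TRUE, prob = w)
  offspring <- pool[idx, ]
  mut <- mutate_pool(offspring, config$mutation, next_lineage)
  offspring <- mut$pool
  n_cheat <- round(config$cheat_injection * n)
  if (n_cheat > 0) {
    slots <- sample.int(n, n_cheat)
    offspring[slots, ] <- make_cheat(n_cheat, config$mutation$bounds)
  }
  rec <- record_row(gen, pool, ev)
  list(pool = offspring, record = rec, next_lineage = mut$next_lineage,
       eval = list(gid = gid, fitness = ev$fitness,
                   investment = ev$investment, parent_idx = idx))
}

#' Run an evolutionary simulation
#'
#' Evolves an initially identical pool for `config$generations`
#' generations. Deterministic given `seed`. The final pool is re-grouped
#' and evaluated once more so assortment and Price analyses can read a
#' consistent final state.
#'
#' @param config a [qs_config()].
#' @param seed integer master seed (required; no silent time seeding).
#' @return An object of class `qs_sim`: list with `records` (tibble, one
#'   row per generation), `final_pool`, `final_gid`, `final_eval`
#'   (fitness/investment of the final pool), `config`, `seed`.
#' @examples
#' sim <- run_simulation(qs_config(pool_size = 50, generations = 5), seed = 1)
#' sim$records
#' @export
run_simulation <- function(config, seed) {
  if (missing(seed)) abort("`seed` is required")
  set.seed(seed)
  pool <- genotype_pool(config$pool_size,
                        p = config$init$p, s_th = config$init$s_th,
                        r = config$init$r %||% 0,
                        bounds = config$mutation$bounds)
  next_lineage <- config$pool_size + 1L
  records <- vector("list", config$generations)
  for (gen in seq_len(config$generations)) {
    step <- run_generation(pool, config, gen, next_lineage)
    pool <- step$pool
    next_lineage <- step$next_lineage
    records[[gen]] <- step$record
  }
  # final-state evaluation for downstream analyses
  gid <- found_groups(pool, config$mixing)
  ev <- eval_engine(pool, gid, config$grid, config$env,
                    config$dynamics, config$payoff)
  structure(list(
    records = dplyr::bind_rows(records),
    final_pool = pool,
    final_gid = gid,
    final_eval = list(fitness = ev$fitness, investment = ev$investment),
    config = config,
    seed = seed
  ), class = "qs_sim")
}

#' @export
print.qs_sim <- function(x, ...) {
  cat(sprintf(
    "<qs_sim> %d individuals x %d generations (seed %d)\n",
    x$config$pool_size, x$config$generations, x$seed))
  last <- dplyr::slice_tail(x$records, n = 1)
  cat(sprintf("  final means: p = %.3g, s_th = %.3g, r = %.3g, payoff = %.1f\n",
              last$mean_p, last$mean_s_th, last$mean_r, last$mean_payoff))
  invisible(x)
}

#' Summarise the last k generations
#'
#' Evolved-mean convention: arithmetic mean (and SD) of every recorded
#' quantity over the final `k` generations.
#'
#' @param x a `qs_sim` or its `records` tibble.
#' @param k window length; default the config's `summary_window` (or 50).
#' @return One-row tibble of means (columns as in the records) plus
#'   `window_sd_*` columns for the trait means and payoff.
#' @export
summarize_last_k <- function(x, k = NULL) {
  records <- if (inherits(x, "qs_sim")) x$records else x
  if (is.null(k)) {
    k <- if (inherits(x, "qs_sim")) x$config$summary_window else 50L
  }
  if (k > nrow(records)) abort("`k` exceeds the number of records")
  tail_rec <- dplyr::slice_tail(records, n = k)
  means <- dplyr::summarise(
    tail_rec,
    dplyr::across(c("mean_p", "mean_s_th", "mean_r", "mean_payoff",
                    "frac_on", "diversity", "cheat_frac"), mean))
  sds <- dplyr::summarise(
    tail_rec,
    dplyr::across(c("mean_p", "mean_s_th", "mean_r", "mean_payoff"),
                  sd, .names = "window_sd_{.col}"))
  dplyr::bind_cols(tibble::tibble(k = k), means, sds)
}

#' Run replicate simulations
#'
#' Independent runs with seeds derived deterministically from a master
#' seed; per-replicate evolved-mean summaries plus across-replicate mean
#' and SD.
#'
#' @param config a [qs_config()].
#' @param n_reps number of replicates.
#' @param seed master seed.
#' @param keep_sims keep the full `qs_sim` objects (memory-heavy)?
#' @return List of class `qs_replicates`: `summaries` (tibble, one row
#'   per replicate), `across` (two-row tibble: mean and SD), `seeds`,
#'   and optionally `sims`.
#' @export
run_replicates <- function(config, n_reps, seed, keep_sims = FALSE) {
  check_num(n_reps, "n_reps", lower = 1)
  seeds <- derive_seeds(seed, n_reps)
  sims <- vector("list", n_reps)
  summaries <- purrr::map(seq_len(n_reps), function(i) {
    sim <- run_simulation(config, seeds[i])
    if (keep_sims) sims[[i]] <<- sim
    k <- min(config$summary_window, config$generations)
    dplyr::bind_cols(tibble::tibble(replicate = i, seed = seeds[i]),
                     summarize_last_k(sim, k))
  })
  summaries <- dplyr::bind_rows(summaries)
  num <- dplyr::select(summaries, -"replicate", -"seed", -"k")
  across <- dplyr::bind_rows(
    dplyr::summarise(num, dplyr::across(dplyr::everything(), mean)),
    dplyr::summarise(num, dplyr::across(dplyr::everything(),
                                        ~ if (dplyr::n() > 1) sd(.x) else 0))
  )
  across$stat <- c("mean", "sd")
  structure(list(summaries = summaries,
                 across = dplyr::relocate(across, "stat"),
                 seeds = seeds,
                 sims = if (keep_sims) sims else NULL),
            class = "qs_replicates")
}
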