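#' Experiment presets
#'
#' Named bundles of configuration encoding the package's study
#' conditions at desk scale (pool 500; generations as noted; 5
#' replicates for the stochastic comparisons):
#'
#' * `"clonal-cost-sweep"`: clonal evolution (G = 1) across a grid of
#'   signalling costs, C_sig from 5e8 to 100e8 in steps of 5e8
#'   (20 levels), 300 generations; used for the signal/response
#'   coordination line.
#' * `"mixing-sweep"`: QS-controlled cooperation (no feedback) across a
#'   ladder of mixing intensities (clonal, then lambda = 1..5), 500
#'   generations, C_sig = 2e9; exhibits the coercion hump and the
#'   high-mixing payoff collapse.
#' * `"mixing-sweep-auto"`: the same ladder with the feedback ratio
#'   evolving, C_sig = 5e8. The lower signalling cost widens the window
#'   in which cooperation survives long enough at this reduced scale for
#'   feedback to evolve; the rescue comparison (r evolving vs r frozen)
#'   is run at lambda = 4.
#' * `"assortment-g5"`: fixed five founders per group, C_sig = 5e8, two
#'   arms (with and without feedback), 120 generations — the snapshot is
#'   taken while cooperation still segregates, since at this scale
#'   five-founder groups eventually lose cooperation in both arms.
#' * `"spandrel-strains"`: three evolved strains assayed against mass
#'   transfer at fixed high density (clonal: p = 4.37e-9, S_Th = 2.15;
#'   intermediate relatedness: p = 9.27e-9, S_Th = 4.63; low
#'   relatedness: p = 8.71e-9, S_Th = 7.27; N = 8.5e4, u = 1e-4).
#' * `"full-scale"`: 5,000 individuals, 5,000 generations, 30
#'   replicates — the headline conditions (hours of compute).
#' * `"reduced"`: 500 individuals, 300 generations, 5 replicates — the
#'   generic desk-scale conditions.
#'
#' @param name preset name.
#' @param scale multiplier applied to pool size and generations
#'   (e.g. `scale = 0.1` for a quick look); minimum sizes enforced.
#' @return A list with a `config` ([qs_config()]) where applicable, plus
#'   preset-specific elements (`c_sig_levels`, `lambda_levels`,
#'   `rescue_lambda`, `strains`, `n_reps`, `arms`).
#' @examples
#' qs_preset("spandrel-strains")$strains
#' @export
qs_preset <- function(name = c("reduced", "clonal-cost-sweep",
                               "mixing-sweep", "mixing-sweep-auto",
                               "assortment-g5", "spandrel-strains",
                               "full-scale"),
                      scale = 1) {
  name <- match.arg(name)
  check_num(scale, "scale", lower = 0, strict_lower = TRUE)
  base_cfg <- function(pool, gens, ...) {
    qs_config(pool_size = max(round(pool * scale), 20),
              generations = max(round(gens * scale), 10), ...)
  }
  switch(name,
    "reduced" = list(
      config = base_cfg(500, 300),
      n_reps = 5),
    "clonal-cost-sweep" = list(
      config = base_cfg(500, 300, mixing = mixing_config(fixed_g = 1)),
      c_sig_levels = seq(5e8, 100e8, by = 5e8),
      n_reps = 1),
    "mixing-sweep" = list(
      config = base_cfg(500, 500,
                        payoff = payoff_params(c_sig = 2e9)),
      lambda_levels = c(NA, 1, 2, 3, 4, 5),   # NA = clonal (fixed G = 1)
      n_reps = 5),
    "mixing-sweep-auto" = list(
      config = base_cfg(500, 500,
                        payoff = payoff_params(mode = "qs_auto",
                                               c_sig = 5e8)),
      lambda_levels = c(NA, 1, 2, 3, 4, 5),
      rescue_lambda = 4,
      n_reps = 5),
    "assortment-g5" = list(
      config = base_cfg(500, 120, mixing = mixing_config(fixed_g = 5),
                        payoff = payoff_params(c_sig = 5e8)),
      arms = c("qs_no_auto", "qs_auto"),
      n_reps = 5),
    "spandrel-strains" = list(
      strains = tibble::tibble(
        strain = c("clonal", "intermediate", "low-relatedness"),
        p = c(4.37e-9, 9.27e-9, 8.71e-9),
        s_th = c(2.15, 4.63, 7.27)),
      n = 8.5e4, u = 1e-4, m_max = 1e-4),
    "full-scale" = list(
      config = base_cfg(5000, 5000),
      n_reps = 30)
  )
}

#' Apply a mixing level to a config
#'
#' Helper for sweep presets: `NA` means the clonal limit (fixed G = 1),
#' a number is the founder-intensity lambda.
#'
#' @param config a [qs_config()].
#' @param lambda numeric lambda, or `NA` for clonal.
#' @return Updated config.
#' @export
with_mixing <- function(config, lambda) {
  config$mixing <- if (is.na(lambda)) mixing_config(fixed_g = 1)
                   else mixing_config(lambda = lambda)
  config
}

#' Switch the cooperation mode of a config
#'
#' Helper for two-arm comparisons: returns the config with the payoff
#' `mode` replaced (the mutation freeze on the feedback ratio is
#' re-derived by [qs_config()]).
#'
#' @param config a [qs_config()].
#' @param mode new payoff mode.
#' @return Updated config.
#' @export
with_mode <- function(config, mode) {
  pay <- config$payoff
  pay$mode <- match.arg(mode, c("qs_no_auto", "qs_auto",
                                "constitutive", "never"))
  mut <- config$mutation
  mut$freeze <- setdiff(mut$freeze, "r")
  qs_config(pool_size = config$pool_size,
            generations = config$generations,
            mixing = config$mixing, mutation = mut, payoff = pay,
            dynamics = config$dynamics, env = config$env,
            grid = config$grid, init = config$init,
            cheat_injection = config$cheat_injection,
            summary_window = config$summary_window)
}
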