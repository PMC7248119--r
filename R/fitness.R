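#' Payoff parameters
#'
#' The payoff of an individual tested at density N within its group is
#'
#' `baseline + [N > N_Th] * B_coop * f  -  [ON] * C_coop  -  C_sig * p_eff`
#'
#' where `f` is the group's cooperating fraction at that density and
#' `p_eff` is the realised per-capita production rate (`p` without
#' auto-regulation, `p (1 + r S*/(K + S*))` with it, so induced feedback
#' production is itself costly). The public-good benefit is shared by all
#' group members in proportion to `f`, and only above the critical
#' density `n_th`; the cooperation cost is paid only while ON.
#'
#' @param baseline payoff of a never-signalling, never-cooperating
#'   individual; default 1000.
#' @param b_coop maximum group benefit; default 300.
#' @param c_coop fixed cost of expressing cooperation; default 100.
#' @param c_sig cost per unit signal production rate; default 2e10.
#' @param n_th critical density threshold (cells/uL); default the median
#'   of the default density grid.
#' @param mode cooperation mode: `"qs_no_auto"` (signal + threshold,
#'   feedback inert), `"qs_auto"` (all three traits active),
#'   `"constitutive"` (always ON, no signalling machinery), or `"never"`
#'   (always OFF; baseline strategy).
#' @return A list of class `qs_payoff`.
#' @export
payoff_params <- function(baseline = 1000, b_coop = 300, c_coop = 100,
                          c_sig = 2e10, n_th = NULL,
                          mode = c("qs_no_auto", "qs_auto",
                                   "constitutive", "never")) {
  mode <- match.arg(mode)
  if (is.null(n_th)) n_th <- median(build_density_grid())
  check_num(baseline, "baseline")
  check_num(b_coop, "b_coop", lower = 0)
  check_num(c_coop, "c_coop", lower = 0)
  check_num(c_sig, "c_sig", lower = 0)
  check_num(n_th, "n_th", lower = 0, strict_lower = TRUE)
  structure(list(baseline = baseline, b_coop = b_coop, c_coop = c_coop,
                 c_sig = c_sig, n_th = n_th, mode = mode),
            class = "qs_payoff")
}

#' Baseline payoff
#'
#' The payoff of the never-signal / never-cooperate strategy, constant
#' across densities. A population of constitutive cheats earns exactly
#' this.
#'
#' @param pay a [payoff_params()].
#' @return Scalar baseline payoff.
#' @export
baseline_payoff <- function(pay) pay$baseline

#' Testing-environment density grid
#'
#' Evenly spaced densities on the linear scale between `low` and `high`
#' inclusive. With the defaults (10^1.5 to 1e5 cells/uL, 100 points) the
#' grid median is 5.0016e4 cells/uL, which doubles as the default
#' critical density threshold.
#'
#' @param low,high grid endpoints (cells/uL), `0 < low < high`.
#' @param count number of environments (>= 2); default 100.
#' @return Numeric vector of densities, strictly increasing.
#' @examples
#' median(build_density_grid())
#' @export
build_density_grid <- function(low = 10^1.5, high = 1e5, count = 100) {
  check_num(low, "low", lower = 0, strict_lower = TRUE)
  check_num(high, "high", lower = low, strict_lower = TRUE)
  check_num(count, "count", lower = 2)
  seq(low, high, length.out = count)
}

# Vectorised evaluation engine shared by evaluate_group() and the
# generational loop. Works on plain vectors/matrices for speed.
#
# pool: list/data frame with p, s_th, r; gid: integer group labels;
# grid: density vector. Returns list with matrices (rows = members,
# cols = densities): on, pay, s_star (group-expanded), plus per-group
# s_star and f matrices, and per-member mean fitness and ON fraction.
eval_engine <- function(pool, gid, grid, env, dyn, pay) {
  n <- length(pool$p)
  d <- length(grid)
  auto <- pay$mode == "qs_auto"
  gsize <- tabulate(gid)
  ngrp <- length(gsize)

  if (pay$mode == "constitutive") {
    on <- matrix(TRUE, n, d)
    f_grp <- matrix(1, ngrp, d)
    s_grp <- matrix(0, ngrp, d)
  } else if (pay$mode == "never") {
    on <- matrix(FALSE, n, d)
    f_grp <- matrix(0, ngrp, d)
    s_grp <- matrix(0, ngrp, d)
  } else {
    # per-group production loads; density split equally over G founders
    sum_p <- rowsum(pool$p, gid, reorder = TRUE)[, 1]
    a_unit <- sum_p / gsize                         # load per unit density
    a <- a_unit %o% grid                            # ngrp x d
    if (auto) {
      sum_pr <- rowsum(pool$p * pool$r, gid, reorder = TRUE)[, 1]
      b <- (sum_pr / gsize) %o% grid
      s_grp <- signal_equilibrium_auto(a, b, dyn, env)
      dim(s_grp) <- c(ngrp, d)
    } else {
      s_grp <- a / (env$u + env$m)
    }
    s_mem <- s_grp[gid, , drop = FALSE]             # n x d
    perceived <- s_mem
    if (env$noise_sd > 0) {
      perceived <- s_mem * exp(matrix(rnorm(n * d, 0, env$noise_sd), n, d))
    }
    on <- perceived > pool$s_th
    f_grp <- rowsum(on + 0, gid, reorder = TRUE) / gsize
  }

  s_mem <- s_grp[gid, , drop = FALSE]
  f_mem <- f_grp[gid, , drop = FALSE]
  supra <- grid > pay$n_th

  benefit <- pay$b_coop * f_mem
  benefit[, !supra] <- 0
  if (pay$mode %in% c("constitutive", "never")) {
    sig_cost <- 0
  } else if (auto) {
    p_eff <- pool$p * (1 + pool$r * s_mem / (dyn$k + s_mem))
    sig_cost <- pay$c_sig * p_eff
  } else {
    sig_cost <- pay$c_sig * pool$p
  }
  paym <- pay$baseline + benefit - pay$c_coop * on - sig_cost

  list(on = on, pay = paym,
       s_star = s_grp, f = f_grp,
       fitness = unname(rowMeans(paym)),
       investment = unname(rowMeans(on)))
}

#' Evaluate a founder group across the density grid
#'
#' Computes, for each density in the grid, the group's equilibrium signal
#' (total production load over founders, with the density split equally
#' among them), each member's ON/OFF decision, the cooperating fraction
#' `f`, and each member's payoff; a member's fitness is its mean payoff
#' over the grid and its cooperative investment is its ON fraction.
#'
#' @param founders a `qs_pool` tibble (the founders of one group).
#' @param grid density grid from [build_density_grid()].
#' @param env a [signal_env()].
#' @param dyn a [dynamics_params()].
#' @param pay a [payoff_params()].
#' @return A list of class `qs_group_eval` with tibbles `members`
#'   (per-member `fitness`, `investment`) and `per_density` (`density`,
#'   `s_star`, `f`), plus the logical ON matrix `on` and payoff matrix
#'   `pay` (members x densities).
#' @export
evaluate_group <- function(founders, grid = build_density_grid(),
                           env = signal_env(), dyn = dynamics_params(),
                           pay = payoff_params()) {
  if (nrow(founders) == 0) abort("founder set is empty")
  gid <- rep.int(1L, nrow(founders))
  ev <- eval_engine(founders, gid, grid, env, dyn, pay)
  structure(list(
    members = tibble::tibble(
      member = seq_len(nrow(founders)),
      p = founders$p, s_th = founders$s_th, r = founders$r,
      fitness = ev$fitness, investment = ev$investment),
    per_density = tibble::tibble(
      density = grid, s_star = ev$s_star[1, ], f = ev$f[1, ]),
    on = ev$on, pay = ev$pay
  ), class = "qs_group_eval")
}

#' Single-observation payoff
#'
#' The payoff of one member at one density, exposed for inspection and
#' testing; the simulator uses the vectorised engine with identical
#' arithmetic.
#'
#' @param member_on logical: is this member ON?
#' @param f cooperating fraction of its group at this density, in `[0,1]`.
#' @param n density (cells/uL).
#' @param p,r member's production rate and auto-regulation ratio.
#' @param s_star group equilibrium signal at this density (uM).
#' @param pay a [payoff_params()].
#' @param dyn a [dynamics_params()].
#' @return Scalar payoff.
#' @export
payoff <- function(member_on, f, n, p, r = 0, s_star = 0,
                   pay = payoff_params(), dyn = dynamics_params()) {
  check_num(f, "f", lower = 0, upper = 1)
  if (pay$mode %in% c("constitutive", "never")) {
    p_eff <- 0
  } else if (pay$mode == "qs_auto") {
    p_eff <- p * (1 + r * s_star / (dyn$k + s_star))
  } else {
    p_eff <- p
  }
  pay$baseline +
    (n > pay$n_th) * pay$b_coop * f -
    member_on * pay$c_coop -
    pay$c_sig * p_eff
}
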