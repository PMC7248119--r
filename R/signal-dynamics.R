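#' Signal environment
#'
#' Describes the abiotic world a sub-population experiences: the stationary
#' cell density `n` (cells/uL, optional here because most routines sweep
#' density over a grid), the signal decay rate `u` (uL/s), an optional
#' mass-transfer loss rate `m` acting as an additional first-order signal
#' sink, and an optional log-normal noise SD on the perceived signal.
#'
#' @param n stationary cell density (cells/uL), or `NULL` when the density
#'   is supplied per-assay (e.g. by a density grid).
#' @param u signal decay rate (uL/s); must be > 0.
#' @param m mass-transfer loss rate, same units as `u`; default 0.
#' @param noise_sd SD of multiplicative log-normal noise on perceived
#'   signal (dimensionless); default 0 (deterministic perception).
#' @return A list of class `qs_env`.
#' @examples
#' signal_env(u = 1e-4)
#' signal_env(n = 8.5e4, u = 1e-4, m = 5e-5)
#' @export
signal_env <- function(n = NULL, u = 1e-4, m = 0, noise_sd = 0) {
  if (!is.null(n)) check_num(n, "n", lower = 0, strict_lower = TRUE)
  check_num(u, "u", lower = 0, strict_lower = TRUE)
  check_num(m, "m", lower = 0)
  check_num(noise_sd, "noise_sd", lower = 0)
  structure(list(n = n, u = u, m = m, noise_sd = noise_sd),
            class = "qs_env")
}

#' Signal-dynamics parameters
#'
#' @param k half-saturation signal concentration (uM) of the positive
#'   feedback loop; must be > 0.
#' @return A list of class `qs_dynamics`.
#' @export
dynamics_params <- function(k = 1) {
  check_num(k, "k", lower = 0, strict_lower = TRUE)
  structure(list(k = k), class = "qs_dynamics")
}

#' Equilibrium signal concentration without auto-regulation
#'
#' Extracellular signal produced at total rate `load` (the sum of p * N
#' contributions over the genotypes sharing the pool, uM/s) and lost by
#' first-order decay `u` plus mass transfer `m` equilibrates at
#' `load / (u + m)`. With `m = 0` this is the familiar `p N / u`.
#'
#' @param load total production load, Sum(p_g N_g), in uM/s. Vectorised.
#' @param env a [signal_env()].
#' @return Equilibrium signal concentration S* (uM).
#' @examples
#' signal_equilibrium(4.37e-9 * 5.0016e4, signal_env(u = 1e-4))
#' @export
signal_equilibrium <- function(load, env = signal_env()) {
  check_num(load, "load", lower = 0)
  load / (env$u + env$m)
}

#' Equilibrium signal concentration with auto-regulation
#'
#' With positive feedback, production is `p (1 + r S / (K + S)) N`; summed
#' over a (possibly heterogeneous) group this splits into a linear load
#' `a = Sum(p_g N_g)` and a feedback load `b = Sum(p_g r_g N_g)`.  Setting
#' production equal to loss gives the quadratic
#' `(u + m) S^2 + ((u + m) K - a - b) S - a K = 0`, whose product of roots
#' is `-aK/(u+m) <= 0`, so there is exactly one non-negative root whenever
#' `a > 0`; that root is returned.  When `b = 0` the result equals
#' [signal_equilibrium()] exactly (bit-for-bit).
#'
#' @param a linear production load Sum(p_g N_g), uM/s. Vectorised.
#' @param b feedback production load Sum(p_g r_g N_g), uM/s. Vectorised.
#' @param dyn a [dynamics_params()] (supplies K).
#' @param env a [signal_env()].
#' @return Equilibrium signal concentration S* (uM).
#' @examples
#' signal_equilibrium_auto(5e-4, 4e-3, dynamics_params(k = 1),
#'                         signal_env(u = 1e-4))
#' @export
signal_equilibrium_auto <- function(a, b, dyn = dynamics_params(),
                                    env = signal_env()) {
  check_num(a, "a", lower = 0)
  check_num(b, "b", lower = 0)
  loss <- env$u + env$m
  k <- dyn$k
  # recycle to common length
  nn <- max(length(a), length(b))
  a <- rep_len(a, nn)
  b <- rep_len(b, nn)
  out <- a / loss                       # exact b == 0 branch
  # with no basal load the only reachable equilibrium is S = 0, even
  # though the quadratic picks up a second root from the feedback term
  act <- b > 0 & a > 0
  if (any(act)) {
    aa <- a[act]; bb <- b[act]
    qb <- loss * k - aa - bb
    disc <- qb^2 + 4 * loss * aa * k
    stopifnot(all(disc >= 0))
    out[act] <- (-qb + sqrt(disc)) / (2 * loss)
  }
  out
}

#' Integrate the signal ODE (non-equilibrium oracle)
#'
#' Numerically integrates `dS/dt = a + b S/(K + S) - (u + m) S` from `s0`
#' over `horizon` seconds. The simulator itself always uses the closed-form
#' equilibria; this integrator exists to check them.
#'
#' @inheritParams signal_equilibrium_auto
#' @param s0 initial signal concentration (uM).
#' @param horizon integration time (s); should be >> 1/(u+m) for the
#'   endpoint to approximate the equilibrium.
#' @param n_steps number of saved time points.
#' @return A tibble with columns `time` and `s`; the last row is the
#'   endpoint.
#' @export
integrate_signal_ode <- function(a, b = 0, dyn = dynamics_params(),
                                 env = signal_env(), s0 = 0,
                                 horizon = 10 / (env$u + env$m),
                                 n_steps = 200) {
  check_num(a, "a", lower = 0)
  check_num(b, "b", lower = 0)
  check_num(s0, "s0", lower = 0)
  check_num(horizon, "horizon", lower = 0, strict_lower = TRUE)
  loss <- env$u + env$m
  k <- dyn$k
  rhs <- function(t, y, parms) {
    list(a + b * y / (k + y) - loss * y)
  }
  times <- seq(0, horizon, length.out = n_steps)
  sol <- deSolve::ode(y = c(s = s0), times = times, func = rhs,
                      parms = NULL, method = "lsoda")
  if (attr(sol, "istate")[1L] < 0) {
    abort(sprintf(
      "signal ODE integration failed (a=%g, b=%g, k=%g, loss=%g, s0=%g)",
      a, b, k, loss, s0))
  }
  tibble::tibble(time = sol[, "time"], s = sol[, "s"])
}

#' Cooperation decision from signal
#'
#' An individual expresses its cooperative phenotype only when the
#' (perceived) equilibrium signal strictly exceeds its response threshold.
#' With `noise_sd > 0` the perceived signal is `s_star` times a log-normal
#' multiplicative error; with `noise_sd = 0` the decision is deterministic
#' and ties are OFF.
#'
#' @param s_star equilibrium signal concentration (uM). Vectorised.
#' @param s_th response threshold (uM). Vectorised.
#' @param noise_sd log-normal noise SD on perceived signal; default 0.
#' @return Logical: `TRUE` = ON (cooperate).
#' @export
response_state <- function(s_star, s_th, noise_sd = 0) {
  check_num(s_star, "s_star", lower = 0)
  check_num(s_th, "s_th", lower = 0)
  perceived <- s_star
  if (noise_sd > 0) {
    nn <- max(length(s_star), length(s_th))
    perceived <- rep_len(s_star, nn) * exp(rnorm(nn, 0, noise_sd))
  }
  perceived > s_th
}

#' Mass-transfer threshold for cooperation
#'
#' At fixed density N, the equilibrium signal `p N / (u + m)` falls with
#' the mass-transfer rate m; cooperation is ON for `m` below
#' `m* = p N / S_Th - u`. If that quantity is not positive the strain
#' never turns on at this density and `NA` is returned.
#'
#' @param p basal signal production rate (uM/s per cell-density unit).
#' @param n cell density (cells/uL).
#' @param u signal decay rate (uL/s).
#' @param s_th response threshold (uM).
#' @return m* (same units as `u`), or `NA_real_` if the strain is never ON.
#' @examples
#' mass_transfer_threshold(4.37e-9, 8.5e4, 1e-4, 2.15)
#' @export
mass_transfer_threshold <- function(p, n, u, s_th) {
  check_num(p, "p", lower = 0, strict_lower = TRUE)
  check_num(n, "n", lower = 0, strict_lower = TRUE)
  check_num(u, "u", lower = 0, strict_lower = TRUE)
  check_num(s_th, "s_th", lower = 0, strict_lower = TRUE)
  m_star <- p * n / s_th - u
  ifelse(m_star > 0, m_star, NA_real_)
}
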