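#' Cooperation-onset curve
#'
#' Fraction of the pool that turns cooperation ON at each testing
#' density. By default each individual is assessed alone (clonal mode:
#' its own signal at full density decides its state), which is how the
#' evolved switch is visualised against the density threshold; pass a
#' group labelling to assess individuals inside their groups instead.
#'
#' @param pool a `qs_pool` tibble.
#' @param grid density grid.
#' @param env,dyn,pay environment, dynamics and payoff settings (the
#'   payoff `mode` decides whether feedback is active and whether the
#'   pool is constitutive).
#' @param gid optional integer group labels (defaults to singletons).
#' @return Tibble with columns `density` and `frac_on`.
#' @export
on_fraction_curve <- function(pool, grid = build_density_grid(),
                              env = signal_env(), dyn = dynamics_params(),
                              pay = payoff_params(), gid = NULL) {
  if (is.null(gid)) gid <- seq_len(nrow(pool))
  ev <- eval_engine(pool, gid, grid, env, dyn, pay)
  out <- tibble::tibble(density = grid, frac_on = colMeans(ev$on))
  class(out) <- c("qs_on_curve", class(out))
  out
}

new_qs_fit <- function(fit, data, extra = list()) {
  structure(c(list(fit = fit, data = data), extra), class = "qs_fit")
}

#' Coordination-line regression
#'
#' Across conditions (e.g. a signalling-cost sweep), evolved mean
#' thresholds track evolved mean production rates along the functional
#' constraint `S_Th = p N_Th / u`: the threshold that makes the switch
#' flip exactly at the critical density. This fits the ordinary least
#' squares line of `s_th` on `p` and reports it next to the
#' parameter-free predicted slope `N_Th / u`.
#'
#' @param points tibble with one row per condition and columns `p` and
#'   `s_th` (evolved means).
#' @param n_th critical density threshold; default the default-grid
#'   median.
#' @param u signal decay rate.
#' @return A `qs_fit` with elements `fit` (the `lm`), `data`,
#'   `predicted_slope` (`n_th/u`); `tidy()`/`glance()` methods apply.
#' @examples
#' pts <- tibble::tibble(p = c(1, 2, 4) * 1e-9,
#'                       s_th = c(1, 2, 4) * 1e-9 * 5.0016e8)
#' glance(constraint_regression(pts))
#' @export
constraint_regression <- function(points,
                                  n_th = median(build_density_grid()),
                                  u = 1e-4) {
  if (nrow(points) < 3) abort("need at least 3 conditions")
  if (var(points$p) == 0) abort("production rates are degenerate (zero variance)")
  fit <- lm(s_th ~ p, data = points)
  new_qs_fit(fit, tibble::as_tibble(points),
             list(predicted_slope = n_th / u,
                  kind = "constraint"))
}

#' Per-individual cooperative investment
#'
#' Investment is operationalised as the fraction of testing densities at
#' which an individual is ON within its group's signal context, so it
#' lies in `[0, 1]`: a constitutive cooperator scores 1, a cheat 0, and
#' a well-tuned clonal genotype about the supra-threshold fraction of
#' the grid.
#'
#' @param pool a `qs_pool` tibble.
#' @param gid integer group labels.
#' @inheritParams on_fraction_curve
#' @return Tibble with columns `group`, `investment` (individual) and
#'   `group_investment` (its group's mean), one row per individual.
#' @export
cooperative_investment <- function(pool, gid, grid = build_density_grid(),
                                   env = signal_env(),
                                   dyn = dynamics_params(),
                                   pay = payoff_params()) {
  ev <- eval_engine(pool, gid, grid, env, dyn, pay)
  inv <- ev$investment
  grp_mean <- tapply(inv, gid, mean)
  tibble::tibble(group = as.integer(gid),
                 investment = inv,
                 group_investment = as.numeric(grp_mean[as.character(gid)]))
}

#' Individual-group assortment regression
#'
#' OLS of group mean investment on individual investment. When every
#' group is internally homogeneous the slope is exactly 1; looser
#' phenotype matching shows up as a shallower slope and larger residual
#' variance.
#'
#' @param investments tibble from [cooperative_investment()] (columns
#'   `investment`, `group_investment`).
#' @return A `qs_fit`; `tidy()`/`glance()` methods apply, and `glance()`
#'   includes the residual variance.
#' @export
assortment_analysis <- function(investments) {
  if (nrow(investments) < 3) abort("need at least 3 individuals")
  if (var(investments$investment) == 0) {
    abort("individual investments are degenerate (zero variance)")
  }
  fit <- lm(group_investment ~ investment, data = investments)
  new_qs_fit(fit, tibble::as_tibble(investments), list(kind = "assortment"))
}

#' Compare two assortment slopes (ANCOVA)
#'
#' Pools the two datasets, fits `group_investment ~ investment * arm`,
#' and tests the interaction term with an F test: a significant
#' interaction means the two regimes differ in how tightly individual
#' behaviour predicts group behaviour.
#'
#' @param fit_a,fit_b `qs_fit` objects from [assortment_analysis()].
#' @return One-row tibble: `slope_a`, `slope_b`, `f_statistic`, `df1`,
#'   `df2`, `p_value`.
#' @export
compare_slopes <- function(fit_a, fit_b) {
  da <- dplyr::mutate(fit_a$data, arm = "a")
  db <- dplyr::mutate(fit_b$data, arm = "b")
  pooled <- dplyr::bind_rows(da, db)
  full <- lm(group_investment ~ investment * arm, data = pooled)
  reduced <- lm(group_investment ~ investment + arm, data = pooled)
  av <- anova(reduced, full)
  tibble::tibble(
    slope_a = coef(fit_a$fit)[["investment"]],
    slope_b = coef(fit_b$fit)[["investment"]],
    f_statistic = av$F[2],
    df1 = av$Df[2],
    df2 = av$Res.Df[2],
    p_value = av$`Pr(>F)`[2]
  )
}

#' Two-level Price decomposition
#'
#' Exact bookkeeping partition of the change in a trait's population
#' mean into between-group selection, `Cov_g(W_g, zbar_g) / Wbar`, and
#' within-group selection plus transmission,
#' `E_g[W_g * (zbar'_g - zbar_g)] / Wbar`, where groups are weighted by
#' their parent counts, `W_g` is the mean realised fitness (offspring
#' count) of group g's parents and `zbar'_g` the mean trait of its
#' offspring. The two terms sum to the realised change in the mean
#' exactly.
#'
#' @param parents tibble with columns `group`, `fitness` (realised
#'   offspring count, or any non-negative weight), `trait`.
#' @param offspring tibble with columns `group` (the parent group each
#'   offspring descends from) and `trait`. Offspring counts per group
#'   must equal the summed parental fitness per group (checked), else
#'   the identity would not be bookkeeping-exact.
#' @return One-row tibble of class `qs_price`: `between`, `within`,
#'   `total`, `mean_fitness`.
#' @export
price_decomposition <- function(parents, offspring) {
  stopifnot(all(c("group", "fitness", "trait") %in% names(parents)),
            all(c("group", "trait") %in% names(offspring)))
  check_num(parents$fitness, "parents$fitness", lower = 0)
  wbar <- mean(parents$fitness)
  if (wbar == 0) abort("mean fitness is zero; no offspring generation exists")

  pg <- dplyr::summarise(dplyr::group_by(parents, .data$group),
                         n = dplyr::n(),
                         w = mean(.data$fitness),
                         z = mean(.data$trait),
                         wsum = sum(.data$fitness), .groups = "drop")
  og <- dplyr::summarise(dplyr::group_by(offspring, .data$group),
                         n_off = dplyr::n(),
                         z_off = mean(.data$trait), .groups = "drop")
  pg <- dplyr::left_join(pg, og, by = "group")
  pg$n_off[is.na(pg$n_off)] <- 0L
  if (!isTRUE(all.equal(pg$wsum, as.numeric(pg$n_off)))) {
    abort("offspring counts per group do not match summed parental fitness")
  }
  # groups with no offspring contribute w = 0 terms; z_off unused there
  pg$z_off[is.na(pg$z_off)] <- pg$z[is.na(pg$z_off)]

  wt <- pg$n / sum(pg$n)
  ew <- sum(wt * pg$w)
  ez <- sum(wt * pg$z)
  between <- sum(wt * (pg$w - ew) * (pg$z - ez)) / wbar
  within <- sum(wt * pg$w * (pg$z_off - pg$z)) / wbar
  zbar_parent <- sum(pg$n * pg$z) / sum(pg$n)
  zbar_off <- mean(offspring$trait)
  out <- tibble::tibble(between = between, within = within,
                        total = zbar_off - zbar_parent,
                        mean_fitness = wbar)
  class(out) <- c("qs_price", class(out))
  out
}

#' Price decomposition of one recorded generation
#'
#' Convenience wrapper turning the `eval` element of [run_generation()]
#' (parent group labels, fitness-independent offspring ancestry) into a
#' Price partition of a chosen trait, using realised offspring counts as
#' fitness.
#'
#' @param pool parent `qs_pool` used in that generation.
#' @param offspring_pool the offspring pool it produced.
#' @param ev the `eval` element returned by [run_generation()].
#' @param trait which trait to partition (`"p"`, `"s_th"`, or `"r"`).
#' @return See [price_decomposition()].
#' @export
price_from_generation <- function(pool, offspring_pool, ev,
                                  trait = c("p", "s_th", "r")) {
  trait <- match.arg(trait)
  counts <- tabulate(ev$parent_idx, nbins = nrow(pool))
  parents <- tibble::tibble(group = ev$gid, fitness = counts,
                            trait = pool[[trait]])
  offspring <- tibble::tibble(group = ev$gid[ev$parent_idx],
                              trait = offspring_pool[[trait]])
  price_decomposition(parents, offspring)
}

#' Mass-transfer (diffusion-sensing) assay
#'
#' Holds density fixed and sweeps the mass-transfer rate m: the
#' equilibrium signal `p N / (u + m)` falls with m, and cooperation is ON
#' only below the threshold `m* = p N / S_Th - u`. Strains evolved purely
#' against a density challenge thereby exhibit diffusion sensing as a
#' byproduct.
#'
#' @param p,s_th strain production rate and threshold.
#' @param n fixed cell density (cells/uL); default 8.5e4.
#' @param u signal decay rate; default 1e-4.
#' @param m_max top of the m sweep; default 1e-4.
#' @param count number of m values.
#' @param r,dyn optional auto-regulation ratio and dynamics (feedback
#'   included in the equilibrium when `r > 0`).
#' @return A tibble of class `qs_spandrel` with columns `m`, `s_star`,
#'   `on`; attributes `m_star` (threshold, `NA` if never ON) and
#'   `strain` (named parameter list).
#' @examples
#' prof <- spandrel_assay(p = 4.37e-9, s_th = 2.15)
#' attr(prof, "m_star")
#' @export
spandrel_assay <- function(p, s_th, n = 8.5e4, u = 1e-4,
                           m_max = 1e-4, count = 200, r = 0,
                           dyn = dynamics_params()) {
  check_num(m_max, "m_max", lower = 0, strict_lower = TRUE)
  m <- seq(0, m_max, length.out = count)
  s_star <- vapply(m, function(mi) {
    env <- signal_env(u = u, m = mi)
    if (r > 0) signal_equilibrium_auto(p * n, p * r * n, dyn, env)
    else signal_equilibrium(p * n, env)
  }, numeric(1))
  out <- tibble::tibble(m = m, s_star = s_star, on = s_star > s_th)
  m_star <- if (r > 0) {
    if (!any(out$on)) NA_real_ else max(out$m[out$on])
  } else {
    mass_transfer_threshold(p, n, u, s_th)
  }
  attr(out, "m_star") <- m_star
  attr(out, "strain") <- list(p = p, s_th = s_th, r = r, n = n, u = u)
  class(out) <- c("qs_spandrel", class(out))
  out
}
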