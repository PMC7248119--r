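test_that("Price identity holds exactly on a hand-built two-group example", {
  # 2 groups x 2 members; fitnesses are realised offspring counts
  parents <- tibble::tibble(group = c(1, 1, 2, 2),
                            fitness = c(1, 2, 2, 3),
                            trait = c(0, 1, 0, 1))
  offspring <- tibble::tibble(
    group = c(1, 1, 1, 2, 2, 2, 2, 2),
    trait = c(1, 1, 0, 1, 1, 1, 0, 0))
  pr <- price_decomposition(parents, offspring)
  oracle <- price_oracle(parents, offspring)
  expect_equal(pr$between, unname(oracle["between"]), tolerance = 1e-12)
  expect_equal(pr$within, unname(oracle["within"]), tolerance = 1e-12)
  expect_equal(pr$between + pr$within, pr$total, tolerance = 1e-12)
})

test_that("Price partition: clonal groups have no within term, flat fitness none at all", {
  # internally identical groups: all selection is between groups
  parents <- tibble::tibble(group = rep(1:3, each = 2),
                            fitness = rep(c(2, 1, 0), each = 2),
                            trait = rep(c(0.9, 0.5, 0.1), each = 2))
  offspring <- tibble::tibble(group = rep(1:3, times = c(4, 2, 0)),
                              trait = rep(c(0.9, 0.5), times = c(4, 2)))
  pr <- price_decomposition(parents, offspring)
  expect_equal(pr$within, 0, tolerance = 1e-12)
  expect_equal(pr$between, pr$total, tolerance = 1e-12)

  # equal fitness and faithful transmission: no selection anywhere
  parents2 <- tibble::tibble(group = c(1, 1, 2, 2), fitness = 1,
                             trait = c(0, 1, 0.2, 0.8))
  offspring2 <- tibble::tibble(group = parents2$group, trait = parents2$trait)
  pr2 <- price_decomposition(parents2, offspring2)
  expect_equal(pr2$between, 0, tolerance = 1e-12)
  expect_equal(pr2$within, 0, tolerance = 1e-12)
})

test_that("Price identity survives fuzzing and matches the oracle", {
  set.seed(21)
  for (i in 1:30) {
    ngrp <- sample(2:8, 1)
    sizes <- sample(1:6, ngrp, replace = TRUE)
    parents <- tibble::tibble(
      group = rep(seq_len(ngrp), sizes),
      fitness = rpois(sum(sizes), 2),
      trait = runif(sum(sizes)))
    if (sum(parents$fitness) == 0) parents$fitness[1] <- 1
    offspring <- tibble::tibble(
      group = rep(parents$group, parents$fitness),
      trait = rep(parents$trait, parents$fitness) +
        rnorm(sum(parents$fitness), 0, 0.01))
    pr <- price_decomposition(parents, offspring)
    expect_equal(pr$between + pr$within, pr$total, tolerance = 1e-10)
    oracle <- price_oracle(parents, offspring)
    expect_equal(pr$between, unname(oracle["between"]), tolerance = 1e-10)
  }
  expect_error(price_decomposition(
    tibble::tibble(group = 1, fitness = 0, trait = 1),
    tibble::tibble(group = integer(), trait = numeric())), "zero")
})

test_that("a recorded generation yields an exact Price partition", {
  cfg <- tiny_config(pool_size = 60, generations = 1,
                     mixing = mixing_config(lambda = 3))
  set.seed(5)
  pool <- genotype_pool(60, p = 1e-8, s_th = 1)
  pool$s_th <- runif(60, 0.5, 2)
  st <- run_generation(pool, cfg, 1L, 100L)
  pr <- price_from_generation(pool, st$pool, st$eval, trait = "s_th")
  expect_equal(pr$between + pr$within, pr$total, tolerance = 1e-10)
})

test_that("coordination-line regression recovers an exact constraint line", {
  n_th <- 5.0016e4; u <- 1e-4
  pts <- tibble::tibble(p = c(1, 2, 4, 6, 8) * 1e-9)
  pts$s_th <- pts$p * n_th / u
  fit <- constraint_regression(pts, n_th = n_th, u = u)
  g <- suppressWarnings(glance(fit))   # lm warns on an exactly perfect fit
  expect_equal(g$r_squared, 1, tolerance = 1e-10)
  expect_equal(g$slope, n_th / u, tolerance = 1e-10)
  expect_equal(g$predicted_slope, 5.0016e8, tolerance = 1e-6)
  # pure noise has no explanatory power
  set.seed(8)
  noise <- tibble::tibble(p = runif(50, 1e-9, 1e-8), s_th = runif(50, 0, 50))
  expect_lt(glance(constraint_regression(noise))$r_squared, 0.2)
  expect_error(constraint_regression(pts[1:2, ]), "at least 3")
  expect_error(constraint_regression(
    tibble::tibble(p = rep(1e-9, 5), s_th = 1:5)), "degenerate")
})

test_that("onset curves: constitutive pools always ON, silent pools never", {
  pool <- genotype_pool(10)
  cur <- on_fraction_curve(pool, pay = payoff_params(mode = "constitutive"))
  expect_true(all(cur$frac_on == 1))
  silent <- genotype_pool(10, p = 0, s_th = 1)
  cur0 <- on_fraction_curve(silent, env = default_env)
  expect_true(all(cur0$frac_on == 0))
  # tuned single genotype: a step at the critical density
  pay <- payoff_params()
  g1 <- genotype_pool(1, p = 4.37e-9,
                      s_th = 4.37e-9 * pay$n_th / default_env$u)
  grid <- build_density_grid()
  cur1 <- on_fraction_curve(g1, grid, default_env, default_dyn, pay)
  expect_identical(cur1$frac_on, as.numeric(grid > pay$n_th))
})

test_that("investment is 1 for constitutives, 0 for cheats, slope 1 when clonal", {
  pay_c <- payoff_params(mode = "constitutive")
  inv_c <- cooperative_investment(genotype_pool(6), rep(1:3, each = 2),
                                  pay = pay_c)
  expect_true(all(inv_c$investment == 1))
  inv_ch <- cooperative_investment(make_cheat(6), rep(1:3, each = 2),
                                   env = default_env)
  expect_true(all(inv_ch$investment == 0))

  # internally homogeneous groups: individual = group mean exactly
  set.seed(13)
  pool <- genotype_pool(40, p = 5e-9)
  pool$s_th <- rep(runif(20, 0.5, 4), each = 2)   # 20 clonal pairs
  inv <- cooperative_investment(pool, rep(1:20, each = 2),
                                env = default_env)
  fit <- assortment_analysis(inv)
  g <- suppressWarnings(glance(fit))
  expect_equal(g$slope, 1, tolerance = 1e-10)
  expect_equal(g$r_squared, 1, tolerance = 1e-10)

  # identical noisy arms: the ANCOVA finds no slope difference
  noisy <- inv
  noisy$group_investment <- noisy$group_investment +
    rnorm(nrow(noisy), 0, 0.05)
  nfit <- assortment_analysis(noisy)
  cmp <- compare_slopes(nfit, nfit)
  expect_lt(abs(cmp$f_statistic), 1e-10)
  expect_gt(cmp$p_value, 0.99)
})

test_that("the mass-transfer profile falls with m and flags the ON region", {
  prof <- spandrel_assay(p = 4.37e-9, s_th = 2.15)
  expect_true(all(diff(prof$s_star) < 0))
  expect_equal(prof$s_star[1], 4.37e-9 * 8.5e4 / 1e-4, tolerance = 1e-12)
  m_star <- attr(prof, "m_star")
  expect_equal(m_star, 7.28e-5, tolerance = 1e-3)
  expect_identical(prof$on, prof$m < m_star)
  # a never-ON strain has no threshold and an empty ON region
  prof0 <- spandrel_assay(p = 1e-9, s_th = 10)
  expect_true(is.na(attr(prof0, "m_star")))
  expect_false(any(prof0$on))
})
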