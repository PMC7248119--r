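test_that("equilibrium without feedback is load over total loss", {
  # printed clonal-strain arithmetic: p N / u at the median test density
  expect_equal(signal_equilibrium(4.37e-9 * 5.0016e4, signal_env(u = 1e-4)),
               2.185699, tolerance = 1e-6)
  expect_identical(signal_equilibrium(0, signal_env(u = 1e-4)), 0)
  # mass transfer adds to the loss rate
  expect_equal(
    signal_equilibrium(4.37e-9 * 8.5e4, signal_env(u = 1e-4, m = 1e-4)),
    4.37e-9 * 8.5e4 / 2e-4, tolerance = 1e-12)
  expect_error(signal_equilibrium(-1, signal_env()), "load")
  expect_error(signal_env(u = 0), "u")
  expect_error(signal_env(n = 5, u = 1e-4, m = -1), "m")
})

test_that("feedback equilibrium solves the quadratic and nests the linear case", {
  env <- signal_env(u = 1e-4)
  dyn <- dynamics_params(k = 1)
  # hand-solved quadratic: 1e-4 S^2 + (1e-4 - 5e-4 - 4e-3) S - 5e-4 = 0
  # => S = (44 + sqrt(1956)) / 2
  expect_equal(signal_equilibrium_auto(5e-4, 4e-3, dyn, env),
               (44 + sqrt(1956)) / 2, tolerance = 1e-12)
  expect_identical(signal_equilibrium_auto(0, 0, dyn, env), 0)
  # zero linear load with positive feedback load still has the trivial root
  expect_identical(signal_equilibrium_auto(0, 3e-3, dyn, env), 0)
  # b = 0 must be bit-identical to the linear equilibrium
  for (a in c(1e-6, 5e-4, 0.3, 7)) {
    expect_identical(signal_equilibrium_auto(a, 0, dyn, env),
                     signal_equilibrium(a, env))
  }
})

test_that("closed-form equilibria agree with the ODE oracle", {
  set.seed(7)
  for (i in 1:50) {
    u <- 10^runif(1, -5, -3)
    m <- sample(c(0, 10^runif(1, -6, -4)), 1)
    k <- 10^runif(1, -1, 1)
    a <- 10^runif(1, -5, -2)
    b <- sample(c(0, 10^runif(1, -5, -2)), 1)
    env <- signal_env(u = u, m = m)
    dyn <- dynamics_params(k = k)
    target <- signal_equilibrium_auto(a, b, dyn, env)
    traj <- integrate_signal_ode(a, b, dyn, env, s0 = 0,
                                 horizon = 50 / (u + m))
    expect_equal(traj$s[nrow(traj)], target, tolerance = 1e-6)
  }
})

test_that("a trajectory started at equilibrium stays there", {
  env <- signal_env(u = 1e-4)
  traj <- integrate_signal_ode(5e-4, 0, dynamics_params(), env,
                               s0 = 5e-4 / 1e-4)
  expect_true(all(abs(traj$s - 5.0) < 1e-6))
})

test_that("feedback equilibrium is monotone in loads, losses and K", {
  set.seed(11)
  base <- list(a = 2e-4, b = 1e-3, k = 1, u = 1e-4, m = 0)
  s0 <- signal_equilibrium_auto(base$a, base$b, dynamics_params(base$k),
                                signal_env(u = base$u, m = base$m))
  for (i in 1:30) {
    eps <- runif(1, 1.01, 3)
    up <- function(a = base$a, b = base$b, k = base$k, u = base$u,
                   m = base$m) {
      signal_equilibrium_auto(a, b, dynamics_params(k),
                              signal_env(u = u, m = m))
    }
    expect_gte(up(a = base$a * eps), s0)
    expect_gte(up(b = base$b * eps), s0)
    expect_lte(up(u = base$u * eps), s0)
    expect_lte(up(m = base$u * (eps - 1)), s0)
    expect_lte(up(k = base$k * eps), s0)
  }
})

test_that("response is ON only above the threshold, strictly", {
  expect_true(response_state(2.19, 2.15))
  expect_false(response_state(2.15, 2.15))   # tie is OFF
  expect_false(response_state(0, 1))
  # noisy perception is stochastic but unbiased in log space
  set.seed(1)
  on <- replicate(2000, response_state(1, 1, noise_sd = 0.5))
  expect_gt(mean(on), 0.4)
  expect_lt(mean(on), 0.6)
})

test_that("mass-transfer threshold matches the printed strain arithmetic", {
  expect_equal(mass_transfer_threshold(4.37e-9, 8.5e4, 1e-4, 2.15),
               4.37e-9 * 8.5e4 / 2.15 - 1e-4, tolerance = 1e-12)
  expect_equal(mass_transfer_threshold(4.37e-9, 8.5e4, 1e-4, 2.15),
               7.28e-5, tolerance = 1e-3)
  expect_equal(mass_transfer_threshold(8.71e-9, 8.5e4, 1e-4, 7.27),
               1.8e-6, tolerance = 0.03)
  # a strain whose threshold exceeds p N / u can never turn on
  expect_true(is.na(mass_transfer_threshold(1e-9, 1e4, 1e-4, 5)))
})
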