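test_that("configs round-trip through YAML losslessly", {
  cfg <- qs_config(pool_size = 120, generations = 40,
                   mixing = mixing_config(lambda = 2.5, law = "ztpois"),
                   mutation = mutation_model(
                     prob = c(p = 0.2, s_th = 0.1, r = 0.05),
                     sd_frac = c(p = 0.01, s_th = 0.03, r = 0.1),
                     freeze = "s_th"),
                   payoff = payoff_params(mode = "qs_auto", c_sig = 7e9),
                   env = signal_env(u = 2e-4, m = 1e-5, noise_sd = 0.1),
                   grid = build_density_grid(100, 2e5, 50),
                   cheat_injection = 0.02)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_qs_config(cfg, path)
  back <- read_qs_config(path)
  expect_equal(quorumsim:::config_to_list(back),
               quorumsim:::config_to_list(cfg))
  # and the round-tripped config reproduces the run exactly
  expect_identical(run_simulation(back, 3)$records,
                   run_simulation(cfg, 3)$records)
})

test_that("config reader rejects unknown keys and foreign schemas", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- tiny_config()
  lst <- quorumsim:::config_to_list(cfg)
  lst$typo_field <- 1
  yaml::write_yaml(lst, path)
  expect_error(read_qs_config(path), "typo_field")
  lst$typo_field <- NULL
  lst$schema_version <- 99
  yaml::write_yaml(lst, path)
  expect_error(read_qs_config(path), "schema")
  lst$schema_version <- 1
  lst$payoff$c_sig <- -5
  yaml::write_yaml(lst, path)
  expect_error(read_qs_config(path), "c_sig")
  expect_error(read_qs_config("no/such/file.yaml"), "not found")
})

test_that("records round-trip through CSV with schema checking", {
  sim <- run_simulation(tiny_config(generations = 4), seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_qs_records(sim, path)
  back <- read_qs_records(path)
  expect_equal(back$mean_p, sim$records$mean_p)
  expect_equal(back$seed, rep(6, 4))
  # tampered schema is refused
  raw <- readr::read_csv(path, show_col_types = FALSE)
  raw$schema_version <- 9
  readr::write_csv(raw, path)
  expect_error(read_qs_records(path), "schema")
})

test_that("presets encode the documented study conditions", {
  sweep <- qs_preset("clonal-cost-sweep")
  expect_length(sweep$c_sig_levels, 20)
  expect_equal(range(sweep$c_sig_levels), c(5e8, 100e8))
  expect_equal(diff(sweep$c_sig_levels)[1], 5e8)
  expect_identical(sweep$config$mixing$fixed_g, 1L)

  g5 <- qs_preset("assortment-g5")
  expect_identical(g5$config$mixing$fixed_g, 5L)
  expect_identical(g5$arms, c("qs_no_auto", "qs_auto"))

  strains <- qs_preset("spandrel-strains")$strains
  expect_identical(nrow(strains), 3L)
  expect_equal(strains$p[1], 4.37e-9)

  full <- qs_preset("full-scale")
  expect_identical(full$config$pool_size, 5000L)
  expect_identical(full$config$generations, 5000L)
  expect_identical(full$n_reps, 30)

  # scale factor shrinks runs for desk use
  small <- qs_preset("reduced", scale = 0.1)
  expect_identical(small$config$pool_size, 50L)
})

test_that("the command-line front end runs and is seed-deterministic", {
  script <- system.file("scripts", "qsim", package = "quorumsim")
  expect_true(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  run_cli <- function(args) {
    system2(rscript, c(script, args), stdout = TRUE, stderr = TRUE)
  }
  for (out in c(out1, out2)) {
    run_cli(c("run", "--preset", "reduced", "--scale", "0.05",
              "--reps", "1", "--seed", "11", "--out", out))
    expect_true(file.exists(file.path(out, "records_rep1.csv")))
    expect_true(file.exists(file.path(out, "summary.json")))
    expect_true(file.exists(file.path(out, "config.yaml")))
  }
  expect_identical(readLines(file.path(out1, "records_rep1.csv")),
                   readLines(file.path(out2, "records_rep1.csv")))

  # spandrel subcommand reproduces the printed-strain profile
  prof_csv <- file.path(out1, "profile.csv")
  msg <- run_cli(c("spandrel", "--p", "4.37e-9", "--sth", "2.15",
                   "--out", prof_csv))
  expect_true(file.exists(prof_csv))
  prof <- readr::read_csv(prof_csv, show_col_types = FALSE)
  expect_true(all(diff(prof$s_star) < 0))
})
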