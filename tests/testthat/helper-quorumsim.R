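# Shared fixtures: tiny configurations that keep unit tests fast.

tiny_config <- function(pool_size = 40, generations = 5, ...) {
  qs_config(pool_size = pool_size, generations = generations,
            grid = build_density_grid(count = 20), ...)
}

default_env <- signal_env(u = 1e-4)
default_dyn <- dynamics_params(k = 1)

# brute-force Price partition used as an independent oracle: direct
# group-by-group sums with no shared code with price_decomposition()
price_oracle <- function(parents, offspring) {
  gs <- split(seq_len(nrow(parents)), parents$group)
  n <- nrow(parents)
  wbar <- sum(parents$fitness) / n
  wg <- vapply(gs, function(i) mean(parents$fitness[i]), numeric(1))
  zg <- vapply(gs, function(i) mean(parents$trait[i]), numeric(1))
  ng <- vapply(gs, length, numeric(1))
  zoffg <- vapply(names(gs), function(g) {
    rows <- offspring$trait[offspring$group == g]
    if (length(rows) == 0) mean(parents$trait[gs[[g]]]) else mean(rows)
  }, numeric(1))
  wt <- ng / n
  between <- (sum(wt * wg * zg) - sum(wt * wg) * sum(wt * zg)) / wbar
  within <- sum(wt * wg * (zoffg - zg)) / wbar
  c(between = between, within = within)
}
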