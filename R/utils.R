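#' @importFrom rlang abort %||% .data
#' @importFrom stats rpois rnorm runif lm anova coef var sd median setNames
#' @importFrom utils head modifyList
NULL

# Validate a scalar (or vector) numeric argument: finite, optionally bounded.
check_num <- function(x, name, lower = -Inf, upper = Inf,
                      allow_zero_len = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0)) {
    abort(sprintf("`%s` must be numeric", name))
  }
  if (any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite (got non-finite value)", name))
  }
  if (strict_lower) {
    if (any(x <= lower)) abort(sprintf("`%s` must be > %g", name, lower))
  } else if (any(x < lower)) {
    abort(sprintf("`%s` must be >= %g", name, lower))
  }
  if (any(x > upper)) abort(sprintf("`%s` must be <= %g", name, upper))
  invisible(x)
}

# Reflect values into [lo, hi]; repeated folding handles large excursions.
reflect_bounds <- function(x, lo, hi) {
  stopifnot(hi > lo)
  out_of <- function(v) any(v < lo | v > hi)
  while (out_of(x)) {
    x <- ifelse(x < lo, 2 * lo - x, x)
    x <- ifelse(x > hi, 2 * hi - x, x)
  }
  x
}

# Derive n child seeds from a master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
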