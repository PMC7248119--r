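#' Genetic-mixing configuration
#'
#' Controls how the propagule pool is split into locally interacting
#' sub-populations each generation. Either a fixed founder count per group
#' (`fixed_g`) or a stochastic founder-count law driven by the intensity
#' parameter `lambda`:
#'
#' * `"max1"` (default): `max(Poisson(lambda), 1)`. Its mean is
#'   `lambda + exp(-lambda)` (2.135 at lambda = 2).
#' * `"ztpois"`: zero-truncated Poisson, mean `lambda / (1 - exp(-lambda))`
#'   (4.073 at lambda = 4).
#'
#' @param lambda founder-intensity parameter (> 0); ignored when `fixed_g`
#'   is given.
#' @param fixed_g fixed number of founders per group (integer >= 1), or
#'   `NULL` for the stochastic law. `fixed_g = 1` is the clonal limit.
#' @param law founder-count law, `"max1"` or `"ztpois"`.
#' @return A list of class `qs_mixing`.
#' @examples
#' mixing_config(lambda = 2)
#' mixing_config(fixed_g = 5)
#' @export
mixing_config <- function(lambda = NULL, fixed_g = NULL,
                          law = c("max1", "ztpois")) {
  law <- match.arg(law)
  if (is.null(lambda) && is.null(fixed_g)) fixed_g <- 1
  if (!is.null(fixed_g)) {
    check_num(fixed_g, "fixed_g", lower = 1)
    fixed_g <- as.integer(fixed_g)
  } else {
    check_num(lambda, "lambda", lower = 0, strict_lower = TRUE)
  }
  structure(list(lambda = lambda, fixed_g = fixed_g, law = law),
            class = "qs_mixing")
}

#' Draw founder counts
#'
#' @param mixing a [mixing_config()].
#' @param n number of draws.
#' @return Integer vector of founder counts, all >= 1.
#' @examples
#' mean(sample_founder_count(mixing_config(lambda = 2), 1e5))
#' @export
sample_founder_count <- function(mixing, n = 1) {
  if (!is.null(mixing$fixed_g)) return(rep.int(mixing$fixed_g, n))
  lam <- mixing$lambda
  if (mixing$law == "max1") {
    pmax(rpois(n, lam), 1L)
  } else {
    # zero-truncated Poisson by inversion on the conditional CDF
    u <- runif(n)
    stats::qpois(stats::ppois(0, lam) + u * (1 - stats::ppois(0, lam)), lam)
  }
}

#' Expected founders per group
#'
#' Analytic mean of the founder-count law; useful for labelling mixing
#' sweeps by mean group size Gbar rather than by lambda.
#'
#' @param mixing a [mixing_config()].
#' @return Expected founder count.
#' @export
mean_founder_count <- function(mixing) {
  if (!is.null(mixing$fixed_g)) return(as.numeric(mixing$fixed_g))
  lam <- mixing$lambda
  switch(mixing$law,
    max1 = lam + exp(-lam),
    ztpois = lam / (1 - exp(-lam))
  )
}

#' Partition a pool into founder groups
#'
#' Shuffles the pool and cuts it into groups whose sizes are drawn from
#' the founder-count law. Every individual lands in exactly one group; if
#' the pool runs out mid-draw the last group takes the remainder (always
#' >= 1 member).
#'
#' @param pool a `qs_pool` tibble (or any data frame with one row per
#'   individual).
#' @param mixing a [mixing_config()].
#' @return Integer vector of group labels, one per pool row.
#' @export
found_groups <- function(pool, mixing) {
  n <- nrow(pool)
  if (n == 0) abort("pool is empty")
  # draw sizes in batches until they cover the pool
  sizes <- integer(0)
  total <- 0L
  expected <- max(mean_founder_count(mixing), 1)
  while (total < n) {
    need <- max(ceiling((n - total) / expected), 16L)
    draw <- sample_founder_count(mixing, need)
    sizes <- c(sizes, draw)
    total <- total + sum(draw)
  }
  csum <- cumsum(sizes)
  last <- which(csum >= n)[1L]
  sizes <- sizes[seq_len(last)]
  sizes[last] <- sizes[last] - (csum[last] - n)   # remainder rule
  if (sizes[last] == 0L) sizes <- sizes[-last]
  gid <- rep.int(seq_along(sizes), sizes)
  sample(gid)                                      # random assignment
}
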