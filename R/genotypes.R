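#' Trait bounds
#'
#' Hard box constraints on the three evolving traits. Mutation reflects at
#' these bounds, so no genotype can ever leave the box.
#'
#' @param p_max maximum basal production rate (uM/s); default 1e-7.
#' @param s_max maximum response threshold (uM); default 50.
#' @param r_max maximum auto-regulation ratio; default 10 (the evolved
#'   ratios of interest sit well inside this box).
#' @return A list of class `qs_bounds`.
#' @export
trait_bounds <- function(p_max = 1e-7, s_max = 50, r_max = 10) {
  check_num(p_max, "p_max", lower = 0, strict_lower = TRUE)
  check_num(s_max, "s_max", lower = 0, strict_lower = TRUE)
  check_num(r_max, "r_max", lower = 0, strict_lower = TRUE)
  structure(list(p_max = p_max, s_max = s_max, r_max = r_max),
            class = "qs_bounds")
}

#' Build a genotype pool
#'
#' A pool is a tibble with one row per individual and columns
#' `p` (basal signal production rate, uM/s), `s_th` (response threshold,
#' uM), `r` (auto-regulation ratio, dimensionless), `immutable` (logical;
#' constitutive cheats never mutate) and `lineage` (integer identity,
#' refreshed on every mutation, used for diversity accounting).
#'
#' @param n number of individuals.
#' @param p,s_th,r founding trait values (recycled).
#' @param immutable logical, recycled; default `FALSE`.
#' @param bounds a [trait_bounds()].
#' @return A tibble of class `qs_pool`.
#' @examples
#' genotype_pool(5, p = 1e-9, s_th = 10)
#' @export
genotype_pool <- function(n, p = 1e-9, s_th = 10, r = 0,
                          immutable = FALSE, bounds = trait_bounds()) {
  check_num(n, "n", lower = 1)
  check_num(p, "p", lower = 0, upper = bounds$p_max)
  check_num(s_th, "s_th", lower = 0, upper = bounds$s_max)
  check_num(r, "r", lower = 0, upper = bounds$r_max)
  out <- tibble::tibble(
    p = rep_len(p, n),
    s_th = rep_len(s_th, n),
    r = rep_len(r, n),
    immutable = rep_len(as.logical(immutable), n),
    lineage = seq_len(n)
  )
  class(out) <- c("qs_pool", class(out))
  out
}

#' Constitutive cheat genotype
#'
#' A cheat produces no signal (`p = 0`), carries the maximal response
#' threshold (so it never turns cooperation on), has no auto-regulation,
#' and is immutable.
#'
#' @param n number of cheats to create.
#' @param bounds a [trait_bounds()] (supplies the maximal threshold).
#' @return A `qs_pool` tibble of `n` cheat rows.
#' @export
make_cheat <- function(n = 1, bounds = trait_bounds()) {
  out <- genotype_pool(n, p = 0, s_th = bounds$s_max, r = 0,
                       immutable = TRUE, bounds = bounds)
  out$lineage <- rep.int(0L, n)          # cheats share one lineage label
  out
}

#' Mutation model
#'
#' Each unfrozen trait of a mutable parent is independently perturbed with
#' probability `prob` by Gaussian noise with SD `sd_frac` times the trait's
#' bound range, then reflected back into the box. Freezing a trait
#' reproduces the constraint experiments (signal-evolving,
#' response-evolving) in which one trait cannot evolve.
#'
#' @param prob per-trait mutation probability per reproduction event;
#'   scalar or named vector over `c("p", "s_th", "r")`.
#' @param sd_frac perturbation SD as a fraction of the trait range; scalar
#'   or named vector. The default is 2% of range for `p` and `s_th` and
#'   10% for `r`: the selected optima of production and threshold sit
#'   within a few default steps of anywhere in their boxes, whereas
#'   useful feedback ratios lie most of the way across the `r` box, so
#'   an equal step fraction would make feedback far less evolvable than
#'   the other traits on the same timescale.
#' @param freeze character vector of trait names that never mutate.
#' @param bounds a [trait_bounds()].
#' @return A list of class `qs_mutation`.
#' @export
mutation_model <- function(prob = 0.1,
                           sd_frac = c(p = 0.02, s_th = 0.02, r = 0.1),
                           freeze = character(), bounds = trait_bounds()) {
  traits <- c("p", "s_th", "r")
  expand <- function(x, name) {
    if (length(x) == 1 && is.null(names(x))) x <- setNames(rep(x, 3), traits)
    if (!all(traits %in% names(x))) {
      abort(sprintf("`%s` must be scalar or named over p, s_th, r", name))
    }
    x[traits]
  }
  prob <- expand(prob, "prob")
  sd_frac <- expand(sd_frac, "sd_frac")
  check_num(prob, "prob", lower = 0, upper = 1)
  check_num(sd_frac, "sd_frac", lower = 0)
  if (!all(freeze %in% traits)) abort("`freeze` must be among p, s_th, r")
  structure(list(prob = prob, sd_frac = sd_frac, freeze = freeze,
                 bounds = bounds),
            class = "qs_mutation")
}

#' Mutate a pool of genotypes
#'
#' Applies the mutation model independently to every row. Immutable rows
#' and frozen traits pass through unchanged. Mutated rows get fresh
#' lineage identifiers starting at `next_lineage`.
#'
#' @param pool a `qs_pool` tibble.
#' @param model a [mutation_model()].
#' @param next_lineage first lineage id to assign to mutated offspring.
#' @return A list with elements `pool` (mutated tibble) and `next_lineage`.
#' @export
mutate_pool <- function(pool, model = mutation_model(),
                        next_lineage = max(pool$lineage) + 1L) {
  b <- model$bounds
  n <- nrow(pool)
  ranges <- c(p = b$p_max, s_th = b$s_max, r = b$r_max)
  mutated_any <- rep(FALSE, n)
  for (tr in c("p", "s_th", "r")) {
    if (tr %in% model$freeze || model$prob[[tr]] == 0) next
    hit <- runif(n) < model$prob[[tr]] & !pool$immutable
    if (!any(hit)) next
    sdv <- model$sd_frac[[tr]] * ranges[[tr]]
    newv <- pool[[tr]][hit] + rnorm(sum(hit), 0, sdv)
    pool[[tr]][hit] <- reflect_bounds(newv, 0, ranges[[tr]])
    mutated_any <- mutated_any | hit
  }
  k <- sum(mutated_any)
  if (k > 0) {
    pool$lineage[mutated_any] <- seq.int(next_lineage, length.out = k)
    next_lineage <- next_lineage + k
  }
  list(pool = pool, next_lineage = as.integer(next_lineage))
}
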