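#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a quorumsim regression fit
#'
#' One row per model term, broom-style.
#'
#' @param x a `qs_fit` from [constraint_regression()] or
#'   [assortment_analysis()].
#' @param ... unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @method tidy qs_fit
#' @export
tidy.qs_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p_value = sm[, "Pr(>|t|)"]
  )
}

#' Glance at a quorumsim regression fit
#'
#' @param x a `qs_fit`.
#' @param ... unused.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`,
#'   `sigma2` (residual variance), `n`, and for coordination-line fits
#'   `predicted_slope` (`N_Th/u`).
#' @method glance qs_fit
#' @export
glance.qs_fit <- function(x, ...) {
  sm <- summary(x$fit)
  out <- tibble::tibble(
    slope = coef(x$fit)[[2]],
    intercept = coef(x$fit)[[1]],
    r_squared = sm$r.squared,
    sigma2 = sm$sigma^2,
    n = nrow(x$data)
  )
  if (!is.null(x$predicted_slope)) out$predicted_slope <- x$predicted_slope
  out
}

#' @export
print.qs_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<qs_fit:%s> slope = %.4g, intercept = %.4g, R^2 = %.4f, n = %d\n",
              x$kind %||% "ols", g$slope, g$intercept, g$r_squared, g$n))
  if (!is.null(x$predicted_slope)) {
    cat(sprintf("  predicted slope (N_Th/u) = %.6g\n", x$predicted_slope))
  }
  invisible(x)
}

#' Glance at a simulation
#'
#' @param x a `qs_sim`.
#' @param ... unused.
#' @return One-row tibble: evolved means over the summary window plus
#'   run dimensions.
#' @method glance qs_sim
#' @export
glance.qs_sim <- function(x, ...) {
  k <- min(x$config$summary_window, nrow(x$records))
  s <- summarize_last_k(x, k)
  dplyr::bind_cols(
    tibble::tibble(pool_size = x$config$pool_size,
                   generations = x$config$generations,
                   seed = x$seed),
    s)
}

#' Tidy a simulation's records
#'
#' Long format: one row per generation x recorded quantity.
#'
#' @param x a `qs_sim`.
#' @param ... unused.
#' @method tidy qs_sim
#' @export
tidy.qs_sim <- function(x, ...) {
  tidyr::pivot_longer(x$records, -"generation",
                      names_to = "quantity", values_to = "value")
}
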