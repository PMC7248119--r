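#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_area
#'   geom_abline geom_vline geom_hline labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a cooperation-onset curve
#'
#' Fraction of individuals ON against testing density, with the critical
#' density marked.
#'
#' @param object a `qs_on_curve` tibble from [on_fraction_curve()].
#' @param n_th critical density to mark; default the default-grid median.
#' @param ... unused.
#' @method autoplot qs_on_curve
#' @export
autoplot.qs_on_curve <- function(object, n_th = median(build_density_grid()),
                                 ...) {
  ggplot(object, aes(x = .data$density, y = .data$frac_on)) +
    geom_line(color = "steelblue") +
    geom_vline(xintercept = n_th, linetype = "dashed") +
    labs(x = "density (cells/uL)", y = "fraction ON",
         title = "Cooperation onset across testing densities") +
    theme_minimal()
}

#' Plot evolution trajectories
#'
#' Trait means and payoff per generation.
#'
#' @param object a `qs_sim`.
#' @param ... unused.
#' @method autoplot qs_sim
#' @export
autoplot.qs_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$records, "generation", "mean_p", "mean_s_th",
                  "mean_r", "mean_payoff"),
    -"generation", names_to = "quantity", values_to = "value")
  ggplot(long, aes(x = .data$generation, y = .data$value)) +
    geom_line() +
    facet_wrap(~quantity, scales = "free_y") +
    labs(x = "generation", y = NULL,
         title = "Evolution trajectory") +
    theme_minimal()
}

#' Plot a mass-transfer assay profile
#'
#' Equilibrium signal against mass-transfer rate with the strain's
#' response threshold and the ON region shaded.
#'
#' @param object a `qs_spandrel` from [spandrel_assay()].
#' @param ... unused.
#' @method autoplot qs_spandrel
#' @export
autoplot.qs_spandrel <- function(object, ...) {
  strain <- attr(object, "strain")
  m_star <- attr(object, "m_star")
  pl <- ggplot(object, aes(x = .data$m, y = .data$s_star)) +
    geom_area(data = dplyr::filter(object, .data$on),
              fill = "tomato", alpha = 0.25) +
    geom_line(color = "blue") +
    geom_hline(yintercept = strain$s_th, linetype = "dashed",
               color = "blue") +
    labs(x = "mass-transfer rate m (uL/s)", y = "S* (uM)",
         title = "Diffusion-sensing profile") +
    theme_minimal()
  if (is.finite(m_star %||% NA_real_)) {
    pl <- pl + geom_vline(xintercept = m_star, linetype = "dashed")
  }
  pl
}

#' Plot an assortment fit
#'
#' Individual vs group-mean cooperative investment with the fitted line.
#'
#' @param object a `qs_fit` from [assortment_analysis()].
#' @param ... unused.
#' @method autoplot qs_fit
#' @export
autoplot.qs_fit <- function(object, ...) {
  if (!identical(object$kind, "assortment")) {
    df <- object$data
    return(
      ggplot(df, aes(x = .data$p, y = .data$s_th)) +
        geom_point(color = "steelblue") +
        geom_abline(slope = coef(object$fit)[[2]],
                    intercept = coef(object$fit)[[1]]) +
        geom_abline(slope = object$predicted_slope, intercept = 0,
                    linetype = "dashed") +
        labs(x = "evolved mean p (uM/s)", y = "evolved mean S_Th (uM)",
             title = "Signal/response coordination line") +
        theme_minimal()
    )
  }
  ggplot(object$data,
         aes(x = .data$investment, y = .data$group_investment)) +
    geom_point(alpha = 0.4, color = "steelblue") +
    geom_abline(slope = coef(object$fit)[[2]],
                intercept = coef(object$fit)[[1]], color = "red") +
    labs(x = "individual investment", y = "group mean investment",
         title = "Individual-group assortment") +
    theme_minimal()
}
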