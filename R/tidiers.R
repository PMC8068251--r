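#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a lognormal fit
#'
#' @param x A `lognormal_fit`.
#' @param ... Unused.
#' @return One-row tibble of estimates: `mu`, `sigma`, `geo_mean_um`,
#'   `r_squared`.
#' @method tidy lognormal_fit
#' @export
tidy.lognormal_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, sigma = x$sigma, geo_mean_um = x$geo_mean,
                 r_squared = x$r_squared)
}

#' Fit-level summary of a lognormal fit
#'
#' @param x A `lognormal_fit`.
#' @param ... Unused.
#' @return One-row tibble: `method`, `n`, `radius_um`, `n_bands`,
#'   `r_squared`, `converged`.
#' @method glance lognormal_fit
#' @export
glance.lognormal_fit <- function(x, ...) {
  tibble::tibble(method = x$method, n = x$n, radius_um = x$radius,
                 n_bands = x$n_bands, r_squared = x$r_squared,
                 converged = x$convergence == 0)
}

#' Tidy a distance histogram
#'
#' @param x A `distance_histogram`.
#' @param ... Unused.
#' @return The band tibble with relative frequencies added.
#' @method tidy distance_histogram
#' @export
tidy.distance_histogram <- function(x, ...) {
  dplyr::mutate(x$bands,
                frequency = ifelse(x$n_within > 0,
                                   .data$count / x$n_within, 0))
}

#' Tidy a composition summary
#'
#' @param x A `composition_summary`.
#' @param ... Unused.
#' @return The per-population summary tibble.
#' @method tidy composition_summary
#' @export
tidy.composition_summary <- function(x, ...) x$summary

#' Plot a banded distance histogram with an optional fitted curve
#'
#' @param object A `distance_histogram`.
#' @param fit Optional `lognormal_fit` overlaid as the truncated model
#'   curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot distance_histogram
#' @export
autoplot.distance_histogram <- function(object, fit = NULL, ...) {
  bands <- tidy(object)
  p <- ggplot2::ggplot(bands, ggplot2::aes(
        x = (.data$lower + .data$upper) / 2, y = .data$frequency)) +
    ggplot2::geom_col(width = diff(object$edges[1:2]) * 0.92,
                      fill = "grey65") +
    ggplot2::labs(x = "nearest-neighbour distance (µm)",
                  y = "relative frequency") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    curve <- tibble::tibble(
      x = (object$edges[-1] + object$edges[-length(object$edges)]) / 2,
      y = band_probs(fit$mu, fit$sigma, object$edges, object$radius)
    )
    p <- p + ggplot2::geom_line(data = curve,
                                ggplot2::aes(x = .data$x, y = .data$y),
                                colour = "firebrick", linewidth = 0.8) +
      ggplot2::labs(subtitle = sprintf(
        "lognormal fit: geometric mean %.2f µm, R² = %.2f",
        fit$geo_mean, fit$r_squared))
  }
  p
}

#' Plot composition frequencies per sample
#'
#' @param object A `composition_summary`.
#' @param ... Unused.
#' @return A ggplot object (stacked per-sample percentage bars).
#' @method autoplot composition_summary
#' @export
autoplot.composition_summary <- function(object, ...) {
  ggplot2::ggplot(object$frequencies, ggplot2::aes(
      x = .data$sample, y = .data$frequency_pct, fill = .data$population)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of parent gate") +
    ggplot2::theme_minimal()
}

#' Plot a phenotyped tissue map
#'
#' @param map Cell-map tibble.
#' @return A ggplot object, faceted by region when several are present.
#' @export
plot_cellmap <- function(map) {
  p <- ggplot2::ggplot(map, ggplot2::aes(
        x = .data$x_um, y = .data$y_um, colour = .data$phenotype)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
  if (length(unique(map$region)) > 1)
    p <- p + ggplot2::facet_wrap(~region)
  p
}
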