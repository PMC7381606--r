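#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_tile
#'   geom_histogram geom_vline labs facet_wrap scale_fill_viridis_c
#'   coord_equal theme_minimal
#' @export
ggplot2::autoplot

#' Plot a quantile fit over the pair scatter
#'
#' Age against latitude with the fitted \eqn{\tau}-quantile line; the upper
#' envelope of the scatter is the quantity of interest, so most points lie
#' below the line by construction.
#'
#' @param object A `quantile_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot quantile_fit
#' @export
autoplot.quantile_fit <- function(object, ...) {
  df <- tibble(latitude = object$x, age_ma = object$y)
  ggplot(df, aes(x = .data$latitude, y = .data$age_ma)) +
    geom_point(alpha = 0.5) +
    geom_abline(intercept = object$coefficients["intercept"],
                slope = object$coefficients["slope"],
                linetype = "dashed") +
    labs(
      x = sprintf("Mean latitude (%s degrees)", object$convention),
      y = "Divergence age (Ma)",
      title = sprintf("%.0fth-quantile age-latitude gradient", 100 * object$tau),
      subtitle = sprintf("slope = %.3g Ma/degree, n = %d",
                         object$coefficients["slope"], object$n)
    ) +
    theme_minimal()
}

#' Plot the two null distributions of a D-statistic run
#'
#' Histograms of the change sums under the tip-shuffle and
#' Brownian-threshold nulls with the observed change sum marked; D
#' places the observation between the two null means.
#'
#' @param object A `dstat_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dstat_result
#' @export
autoplot.dstat_result <- function(object, ...) {
  df <- bind_rows(
    tibble(null = "random (tip shuffle)", d = object$d_random),
    tibble(null = "Brownian threshold", d = object$d_brownian)
  )
  ggplot(df, aes(x = .data$d)) +
    geom_histogram(bins = 40) +
    geom_vline(xintercept = object$d_obs, linetype = "dashed") +
    facet_wrap(~null, ncol = 1, scales = "free_y") +
    labs(x = "Sum of sister-clade differences", y = "Replicates",
         title = sprintf("D = %.3f (dashed: observed)", object$D)) +
    theme_minimal()
}

#' Map a layer of an age grid
#'
#' @param object An `age_grid`.
#' @param layer Column to map (`"mean_age"`, `"richness"`,
#'   `"predicted_age"`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot age_grid
#' @export
autoplot.age_grid <- function(object, layer = "mean_age", ...) {
  stopifnot(layer %in% names(object))
  res <- attr(object, "resolution")
  ggplot(as_tibble(object),
         aes(x = .data$cell_lon, y = .data$cell_lat,
             fill = .data[[layer]])) +
    geom_tile(width = res, height = res) +
    scale_fill_viridis_c(name = layer) +
    coord_equal() +
    labs(x = "Longitude", y = "Latitude") +
    theme_minimal()
}
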