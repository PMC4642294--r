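#' Plot a detection function
#'
#' Detection probability against horizontal range with a +/- one standard
#' deviation ribbon, in the style of the simulation's range-binned output.
#'
#' @param object A `pam_detection_function`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pam_detection_function <- function(object, ...) {
  df <- object$bins
  ggplot2::ggplot(df, ggplot2::aes(x = .data$range_m / 1000, y = .data$prob)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = pmax(0, .data$prob - .data$sd),
        ymax = pmin(1, .data$prob + .data$sd)
      ),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Horizontal range (km)", y = "Detection probability",
      title = sprintf(
        "%s detection, %s (p_k = %.3f)", object$mode,
        object$scenario$label, object$p_k
      )
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot a weekly density series
#'
#' Weekly point estimates with lognormal interval bars, faceted by site when
#' several sites are present.
#'
#' @param series Output of [weekly_series()].
#' @return A ggplot object.
#' @export
plot_density_series <- function(series) {
  p <- ggplot2::ggplot(series, ggplot2::aes(
    x = .data$week_start,
    y = .data$density_per_1000km2
  )) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      size = 0.25
    ) +
    ggplot2::labs(
      x = NULL, y = "Density (animals / 1000 km²)",
      title = paste(unique(series$species), collapse = ", ")
    ) +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(series$site) > 1) {
    p <- p + ggplot2::facet_wrap(~site, ncol = 1)
  }
  p
}
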