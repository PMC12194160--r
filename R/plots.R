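#' Heatmap of a window scan
#'
#' Visualizes the absolute Spearman correlation of every candidate window of
#' one climatic variable as a duration x position tile map, marking the
#' selected (maximal) window.
#'
#' @param scanned Output of [scan_windows()].
#' @return A ggplot object.
#' @export
plot_window_scan <- function(scanned) {
  best <- scanned |>
    dplyr::filter(!is.na(.data$rho)) |>
    dplyr::arrange(dplyr::desc(abs(.data$rho))) |>
    dplyr::slice(1)
  ggplot2::ggplot(scanned,
                  ggplot2::aes(x = .data$months_back, y = .data$duration,
                               fill = abs(.data$rho))) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = best, shape = 21, size = 3,
                        fill = "white") +
    ggplot2::scale_fill_viridis_c(name = "|rho|", na.value = "grey85") +
    ggplot2::labs(
      x = "window end (months before season reference month)",
      y = "window duration (months)",
      title = sprintf("Window scan: %s", scanned$variable[1])
    ) +
    ggplot2::theme_minimal()
}

#' Seasonal abundance time series
#'
#' Yearly seasonal mean abundance per species and season, on a log10 axis.
#'
#' @param abundance Output of [seasonal_abundance()].
#' @return A ggplot object.
#' @export
plot_seasonal_abundance <- function(abundance) {
  ggplot2::ggplot(abundance,
                  ggplot2::aes(x = .data$season_year, y = .data$value,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$season)) +
    ggplot2::labs(x = "season-year", y = "mean monthly count (log scale)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted temporal trend
#'
#' Observed values against (centred) year with the fitted trend curve.
#'
#' @param object A `trend_fit` from [fit_trend()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, ...) {
  d <- object$data
  d$year <- d$.yr + object$year_center
  d$fitted <- stats::fitted(object$fit)
  if (object$family == "quasipoisson") d$fitted <- exp(predict(object$fit))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$.y)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(x = "year", y = object$response) +
    ggplot2::theme_minimal()
}
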