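#' Plot a season partition over its fitted annual curve
#'
#' @param object A `season_partition`.
#' @param curve Optionally the `annual_curve` it was derived from, to draw
#'   the fitted temperature line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.season_partition <- function(object, curve = NULL, ...) {
  p <- ggplot2::ggplot(object$table,
                       ggplot2::aes(x = .data$month, y = 0,
                                    fill = .data$season)) +
    ggplot2::geom_tile(height = Inf, alpha = 0.25) +
    ggplot2::geom_vline(xintercept = mean(object$rise_interval),
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = mean(object$fall_interval),
                        linetype = 2) +
    ggplot2::scale_x_continuous(breaks = 1:12, labels = month.abb) +
    ggplot2::labs(x = NULL, y = "Temperature (°C)",
                  fill = "Season") +
    ggplot2::theme_minimal()
  if (!is.null(curve)) {
    g <- seq(1, 12, 0.05)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(month = g, temp = curve$f(g)),
      ggplot2::aes(x = .data$month, y = .data$temp), inherit.aes = FALSE)
  }
  p
}

#' Forest-style plot of response ratios
#'
#' @param object An `rr_records` tibble from [response_ratio()].
#' @param ... Unused.
#' @return A ggplot object: point estimates with 95% CI bars per unit,
#'   faceted by scope.
#' @export
autoplot.rr_records <- function(object, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), !.data$degenerate)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rr, y = .data$unit,
                                    colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             linewidth = 0.4, size = 0.2) +
    ggplot2::facet_wrap(~scope) +
    ggplot2::labs(x = "Response ratio ln(warmed/control)", y = NULL,
                  colour = "CI excludes 0") +
    ggplot2::theme_minimal()
}

#' Plot daily simulation output
#'
#' @param object A `mend_sim` or `teco_sim` tibble.
#' @param what Columns to draw (default respiration).
#' @param ... Unused.
#' @return A ggplot object of the selected daily series.
#' @export
autoplot.mend_sim <- function(object, what = "rh_umol", ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::select("day", dplyr::all_of(what)) |>
    tidyr::pivot_longer(-"day")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "Day", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mend_sim
#' @export
autoplot.teco_sim <- autoplot.mend_sim

#' Plot a CUE temperature-sensitivity report
#'
#' Daily CUE against temperature per treatment with the crossover
#' temperature marked (when inside the observed range).
#'
#' @param object A `cue_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cue_report <- function(object, ...) {
  p <- ggplot2::ggplot(object$series,
                       ggplot2::aes(x = .data$temperature, y = .data$cue,
                                    colour = .data$treatment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Soil temperature (°C)",
                  y = "Intrinsic CUE (Yg)", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.na(object$crossover))
    p <- p + ggplot2::geom_vline(xintercept = object$crossover,
                                 linetype = 2)
  p
}
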