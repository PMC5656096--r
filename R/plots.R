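# ggplot2 methods for the result containers.

#' Plot population profiles of a trajectory
#'
#' Population against position for a selection of snapshot times (by
#' default six, evenly spaced), averaged over realisations.
#'
#' @param object A `wave_trajectory`.
#' @param times Snapshot times to draw (default: six evenly spaced).
#' @param what `"N"` (population) or `"c"` (oxygen).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wave_trajectory
#' @export
autoplot.wave_trajectory <- function(object, times = NULL, what = c("N", "c"),
                                     ...) {
  what <- match.arg(what)
  tt <- sort(unique(object$time))
  if (is.null(times)) times <- tt[unique(round(seq(1, length(tt), length.out = 6)))]
  df <- object |>
    dplyr::filter(.data$time %in% times) |>
    dplyr::group_by(.data$time, .data$compartment, .data$x_mm) |>
    dplyr::summarise(value = mean(.data[[what]]), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$value,
                                   colour = factor(.data$time))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (mm)",
                  y = if (what == "N") "cells per compartment" else "oxygen (uM)",
                  colour = "time (min)",
                  title = paste("model:", attr(object, "model"))) +
    ggplot2::theme_minimal()
}

#' Plot a front trajectory and its velocity fit
#'
#' @param object A `front_trajectory`.
#' @param fit Optional [front_velocity()] fit to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot front_trajectory
#' @export
autoplot.front_trajectory <- function(object, fit = NULL, ...) {
  gg <- ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$position)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)",
                  y = paste0("front position (", attr(object, "units") %||%
                               "compartment", ")"),
                  title = paste("model:", attr(object, "model"))) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    gg <- gg + ggplot2::geom_abline(intercept = coef(fit$fit)[1],
                                    slope = fit$velocity,
                                    colour = "red", linetype = 2)
  }
  gg
}

#' Plot birth-rate distributions behind and ahead of the interface
#'
#' @param pdf_tbl Output of [birth_rate_pdf()].
#' @param times Snapshot times to facet (default: three, evenly spaced).
#' @return A ggplot object; the vertical line marks the equilibrium birth
#'   rate.
#' @export
plot_birth_rate_pdf <- function(pdf_tbl, times = NULL) {
  tt <- sort(unique(pdf_tbl$time))
  if (is.null(times)) times <- tt[unique(round(seq(1, length(tt), length.out = 3)))]
  df <- pdf_tbl[pdf_tbl$time %in% times, ]
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$bin_mid, .data$mass)) +
    ggplot2::geom_col(width = diff(range(df$bin_mid)) / 40) +
    ggplot2::facet_grid(region ~ time) +
    ggplot2::labs(x = "empirical birth rate (/min)", y = "probability mass") +
    ggplot2::theme_minimal()
  if (!is.null(attr(pdf_tbl, "B_eq"))) {
    gg <- gg + ggplot2::geom_vline(xintercept = attr(pdf_tbl, "B_eq"),
                                   colour = "red", linetype = 2)
  }
  gg
}
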