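# Front statistics: position, velocity, empirical birth rate, and
# birth-rate fluctuation diagnostics.

#' Front position of a population profile
#'
#' The front position is the mean coordinate of the compartments whose
#' population lies strictly between 0 and `K - 100` (transition-zone rule).
#' "Greater than 0" means at least one cell for integer profiles; for
#' real-valued (mean-field) profiles a small tolerance `tol` stands in for
#' zero.
#'
#' @param N Population profile.
#' @param K Carrying capacity (must exceed 100).
#' @param x Compartment coordinates (default: 1-based indices).
#' @param tol Positivity tolerance for real-valued profiles.
#' @return The mean qualifying coordinate, or `NA` if no compartment
#'   qualifies.
#' @export
front_position <- function(N, K, x = seq_along(N), tol = 1e-9) {
  if (K <= 100) stop("`K` must exceed 100 for the K - 100 rule")
  sel <- N > tol & N < (round(K) - 100)
  if (!any(sel)) return(NA_real_)
  mean(x[sel])
}

#' Front-position time series of a trajectory
#'
#' Applies [front_position()] to every snapshot, optionally averaging the
#' position across realisations at common snapshot times (the standard
#' treatment before fitting a wave speed).
#'
#' @param traj A `wave_trajectory` (or any tibble with `realisation`,
#'   `time`, `compartment`, `N` columns).
#' @param K Carrying capacity; defaults to the trajectory's `K` attribute.
#' @param collapse Average across realisations (default `TRUE`).
#' @param units `"compartment"` (1-based lattice index) or `"mm"`.
#' @return A `front_trajectory` tibble with columns `time`, `position`
#'   (plus `realisation` when `collapse = FALSE`).
#' @export
front_trajectory <- function(traj, K = attr(traj, "K"), collapse = TRUE,
                             units = c("compartment", "mm")) {
  units <- match.arg(units)
  if (is.null(K)) stop("supply `K` (no K attribute on the trajectory)")
  xcol <- if (units == "mm") "x_mm" else "compartment"
  ft <- traj |>
    dplyr::group_by(.data$realisation, .data$time) |>
    dplyr::summarise(
      position = front_position(.data$N, K, x = .data[[xcol]]),
      .groups = "drop")
  n_real <- length(unique(ft$realisation))
  if (collapse) {
    ft <- ft |>
      dplyr::group_by(.data$time) |>
      dplyr::summarise(position = mean(.data$position, na.rm = TRUE),
                       .groups = "drop")
  }
  structure(ft, model = attr(traj, "model"), n_real = n_real,
            units = units, K = K,
            class = c("front_trajectory", class(ft)))
}

#' Front velocity by least squares
#'
#' Ordinary least-squares slope of front position against time over a fit
#' window, by default the latter half of the trajectory (to skip the initial
#' transient).  Requires at least 10 points in the window.
#'
#' @param ft A [front_trajectory()] tibble (collapsed across realisations).
#' @param window Fraction of the time range to fit, as `c(from, to)` in
#'   `[0, 1]`; default `c(0.5, 1)`.
#' @return A `front_fit` object with `velocity`, `se`, the `lm` fit, the
#'   window and metadata; see [tidy.front_fit()].
#' @export
front_velocity <- function(ft, window = c(0.5, 1)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  ft <- ft[is.finite(ft$position), ]
  tr <- range(ft$time)
  lo <- tr[1] + window[1] * diff(tr)
  hi <- tr[1] + window[2] * diff(tr)
  sub <- ft[ft$time >= lo & ft$time <= hi, ]
  if (nrow(sub) < 10) stop("fewer than 10 front positions in the fit window")
  fit <- lm(position ~ time, data = sub)
  sm <- suppressWarnings(summary(fit))   # exact fits warn harmlessly
  structure(list(velocity = unname(coef(fit)[2]),
                 se = sm$coefficients["time", "Std. Error"],
                 r_squared = sm$r.squared,
                 fit = fit, window = c(lo, hi), n = nrow(sub),
                 model = attr(ft, "model"), units = attr(ft, "units"),
                 n_real = attr(ft, "n_real")),
            class = "front_fit")
}

#' @export
print.front_fit <- function(x, ...) {
  cat(sprintf("<front_fit> v = %.6g +- %.2g %s/min (R^2 = %.4f, n = %d)\n",
              x$velocity, x$se, x$units %||% "compartment", x$r_squared, x$n))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tidiers for front velocity fits
#'
#' @param x A `front_fit` object.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient-style summary (velocity and
#'   standard error); `glance()`: one-row model summary.
#' @method tidy front_fit
#' @export
tidy.front_fit <- function(x, ...) {
  tibble::tibble(term = "velocity", estimate = x$velocity,
                 std.error = x$se)
}

#' @rdname tidy.front_fit
#' @method glance front_fit
#' @export
glance.front_fit <- function(x, ...) {
  tibble::tibble(velocity = x$velocity, se = x$se, r.squared = x$r_squared,
                 n = x$n, model = x$model %||% NA_character_)
}

#' Empirical (instantaneous) birth rate of a compartment
#'
#' The fraction of cells beyond the G1/S threshold times the division rate:
#' `(mature / N) / tau_p`.  Optionally rescaled by the death rate to the
#' dimensionless representation.
#'
#' @param N Total population (vectorised).
#' @param mature Number of cells at or beyond the threshold age.
#' @param tau_p Division waiting time (minutes).
#' @param dimensionless Divide by `nu` (default `FALSE`).
#' @param nu Death rate, required if `dimensionless`.
#' @return Birth rate per minute (or in death-rate units); `NA` where
#'   `N == 0`.
#' @export
empirical_birth_rate <- function(N, mature, tau_p, dimensionless = FALSE,
                                 nu = NULL) {
  out <- ifelse(N > 0, (mature / N) / tau_p, NA_real_)
  if (dimensionless) {
    if (is.null(nu)) stop("`nu` is required for the dimensionless form")
    out <- out / nu
  }
  out
}

#' Birth-rate distribution behind / ahead of the interface
#'
#' Histograms of the per-compartment empirical birth rate, per snapshot,
#' split at the interface: `"behind"` collects compartments left of the
#' interface, `"ahead"` the interface and everything right of it.  For
#' trajectories without an interface column (the full model), the interface
#' is located diagnostically with [locate_interface()].
#'
#' @param traj A `wave_trajectory` with a `mature` column.
#' @param region `"behind"`, `"ahead"` or `"both"`.
#' @param bins Number of histogram bins.
#' @param theta Threshold for the diagnostic interface (default: the
#'   trajectory's `theta` attribute, else `K/2`).
#' @return A long tibble: `time`, `region`, `bin_mid`, `mass`, plus the
#'   equilibrium birth rate `B_eq` (at the equilibrium oxygen) as an
#'   attribute and column for reference.
#' @export
birth_rate_pdf <- function(traj, region = c("both", "behind", "ahead"),
                           bins = 30, theta = NULL) {
  region <- match.arg(region)
  if (all(is.na(traj$mature))) stop("trajectory has no mature-count column")
  p <- attr(traj, "params")
  if (is.null(theta)) theta <- attr(traj, "theta") %||% (attr(traj, "K") / 2)
  df <- traj |>
    dplyr::group_by(.data$realisation, .data$time) |>
    dplyr::mutate(iface = if (all(is.na(.data$interface))) {
      locate_interface(.data$N, theta)
    } else .data$interface[1]) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$N > 0, !is.na(.data$iface)) |>
    dplyr::mutate(
      B_emp = empirical_birth_rate(.data$N, .data$mature, p$tau_p),
      side = ifelse(.data$compartment < .data$iface, "behind", "ahead"))
  if (region != "both") df <- df[df$side == region, ]
  brks <- seq(0, 1 / p$tau_p, length.out = bins + 1)
  out <- df |>
    dplyr::mutate(bin = cut(.data$B_emp, brks, include.lowest = TRUE)) |>
    dplyr::count(.data$time, .data$side, .data$bin, name = "n") |>
    dplyr::group_by(.data$time, .data$side) |>
    dplyr::mutate(mass = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(bin_mid = brks[as.integer(.data$bin)] + diff(brks)[1] / 2) |>
    dplyr::select("time", region = "side", "bin_mid", "mass")
  B_eq <- attr(traj, "B_eq")
  if (is.null(B_eq) && !is.null(p) && "c" %in% names(traj)) {
    scn_cinf <- traj$c[traj$time == min(traj$time)][1]
    A <- age_g1s(scn_cinf, p$cellcycle, p$p6p3)
    B_eq <- equilibrium_birth_rate(growth_rate(A, p$nu, p$tau_p))
  }
  attr(out, "B_eq") <- B_eq
  out
}

#' Coefficient of variation of the empirical birth rate by region
#'
#' Summarises birth-rate fluctuations behind vs ahead of the interface: the
#' coefficient of variation of the per-compartment empirical birth rate,
#' pooled over snapshots in the latter half of the run.
#'
#' @inheritParams birth_rate_pdf
#' @return A tibble with `region`, `mean`, `sd`, `cv`, `n`.
#' @export
birth_rate_cv <- function(traj, theta = NULL) {
  p <- attr(traj, "params")
  if (is.null(theta)) theta <- attr(traj, "theta") %||% (attr(traj, "K") / 2)
  tmin <- min(traj$time) + 0.5 * diff(range(traj$time))
  traj |>
    dplyr::filter(.data$time >= tmin) |>
    dplyr::group_by(.data$realisation, .data$time) |>
    dplyr::mutate(iface = if (all(is.na(.data$interface))) {
      locate_interface(.data$N, theta)
    } else .data$interface[1]) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$N > 0, !is.na(.data$iface)) |>
    dplyr::mutate(
      B_emp = empirical_birth_rate(.data$N, .data$mature, p$tau_p),
      region = ifelse(.data$compartment < .data$iface, "behind", "ahead")) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(mean = mean(.data$B_emp), sd = sd(.data$B_emp),
                     cv = sd(.data$B_emp) / mean(.data$B_emp),
                     n = dplyr::n(), .groups = "drop")
}

#' Compare front velocities across models
#'
#' Pairwise absolute relative differences `|v_a - v_b| / v_ref`, with the
#' full-model velocity as the reference when present (otherwise the first
#' fit).  When per-realisation front trajectories are supplied, a bootstrap
#' over realisations gives confidence intervals.
#'
#' @param fits A named list of `front_fit` objects.
#' @param boot Optional named list of per-realisation velocity vectors for
#'   bootstrap confidence intervals.
#' @param n_boot Number of bootstrap resamples.
#' @return A tibble with one row per ordered pair: `model_a`, `model_b`,
#'   `v_a`, `v_b`, `rel_diff` (fraction of the reference velocity), and
#'   bootstrap CI columns when available.
#' @export
compare_velocities <- function(fits, boot = NULL, n_boot = 1000) {
  stopifnot(length(fits) >= 2)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$model %||% "model", "")
  }
  v <- vapply(fits, function(f) f$velocity, 0)
  ref_name <- if ("full" %in% names(v)) "full" else names(v)[1]
  v_ref <- v[[ref_name]]
  pairs <- utils::combn(names(v), 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    tibble::tibble(model_a = pr[1], model_b = pr[2],
                   v_a = v[[pr[1]]], v_b = v[[pr[2]]],
                   rel_diff = abs(v[[pr[1]]] - v[[pr[2]]]) / abs(v_ref),
                   reference = ref_name)
  })
  if (!is.null(boot)) {
    ci <- purrr::map_dfr(pairs, function(pr) {
      if (!all(pr %in% names(boot)) || !(ref_name %in% names(boot))) {
        return(tibble::tibble(ci_lo = NA_real_, ci_hi = NA_real_))
      }
      reps <- replicate(n_boot, {
        va <- mean(sample(boot[[pr[1]]], replace = TRUE))
        vb <- mean(sample(boot[[pr[2]]], replace = TRUE))
        vr <- mean(sample(boot[[ref_name]], replace = TRUE))
        abs(va - vb) / abs(vr)
      })
      tibble::tibble(ci_lo = unname(quantile(reps, 0.025)),
                     ci_hi = unname(quantile(reps, 0.975)))
    })
    out <- dplyr::bind_cols(out, ci)
  }
  out
}
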