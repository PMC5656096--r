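#' Cell-cycle parameters
#'
#' Constants of the oxygen-dependent age at the G1/S transition.  The age law
#' has two branches selected by the enzyme momenta ratio p6/p3 relative to
#' the critical ratio `r_cr`:
#'
#' * `p6p3 > r_cr` (no quiescence): `a_G1S(c) = a_plus * exp(-c/c0)`;
#' * `p6p3 < r_cr`: `a_G1S(c) = a_minus * (c/c_cr - 1)^(-beta)` for
#'   `c > c_cr`, and `+Inf` (quiescence) for `c <= c_cr`, where the critical
#'   oxygen `c_cr` comes from [critical_oxygen()].
#'
#' The numeric values of `c0`, `a_plus`, `a_minus`, `beta` and the kinetic
#' constants are not pinned by the growth model itself (they summarise a
#' stochastic cell-cycle model fitted elsewhere); the defaults here are
#' placeholders, and every shipped scenario pins the branch prefactor with
#' [calibrate_cell_cycle()] so results depend only on the calibrated
#' equilibrium, not on the placeholders.
#'
#' @param c0 Oxygen scale of the exponential branch (uM).
#' @param a_plus Prefactor of the exponential branch (minutes).
#' @param a_minus Prefactor of the quiescence branch (minutes).
#' @param beta Exponent of the quiescence branch.
#' @param r_cr Critical p6/p3 ratio separating the branches.
#' @param ccr Named list of kinetic constants `a0, a1, a2, a3, d1, d2,
#'   beta1, e2f_t, H0` entering [critical_oxygen()].
#' @return An object of class `cellcycle_params`.
#' @export
cellcycle_params <- function(c0 = 1, a_plus = 2e4, a_minus = 1e3, beta = 1,
                             r_cr = 0.5,
                             ccr = list(a0 = 0.1, a1 = 1, a2 = 1, a3 = 1,
                                        d1 = 1, d2 = 1, beta1 = 1,
                                        e2f_t = 1, H0 = 1)) {
  stopifnot(c0 > 0, a_plus > 0, a_minus > 0, beta > 0, r_cr > 0)
  structure(list(c0 = c0, a_plus = a_plus, a_minus = a_minus, beta = beta,
                 r_cr = r_cr, ccr = ccr),
            class = "cellcycle_params")
}

#' Critical oxygen concentration for quiescence
#'
#' Evaluates the critical oxygen level below which cells on the
#' `p6p3 < r_cr` branch become quiescent:
#' `c_cr = 1 - (1/beta1) * log( (1/(a3*H0)) * (a1 + a2*(d2/d1)*e2f_t *
#' (1 - 1/(1 - a0*(p3/p6)^2))) )` in the units of the underlying kinetic
#' model.
#'
#' @param p6p3 Enzyme momenta ratio p6/p3.
#' @param ccr Named list of kinetic constants (see [cellcycle_params()]).
#' @return `c_cr` (same oxygen units as the kinetic model, uM here).
#' @export
critical_oxygen <- function(p6p3, ccr) {
  r2 <- ccr$a0 * (1 / p6p3)^2
  if (r2 >= 1) {
    stop("domain error in critical_oxygen: a0*(p3/p6)^2 >= 1 ",
         "(the factor 1 - a0*(p3/p6)^2 must be positive)")
  }
  inner <- ccr$a1 + ccr$a2 * (ccr$d2 / ccr$d1) * ccr$e2f_t * (1 - 1 / (1 - r2))
  arg <- inner / (ccr$a3 * ccr$H0)
  if (!is.finite(arg) || arg <= 0) {
    stop("domain error in critical_oxygen: argument of the outer log ",
         "is non-positive")
  }
  1 - log(arg) / ccr$beta1
}

#' Age at the G1/S transition
#'
#' The oxygen-dependent mean first-passage time to the G1/S cell-cycle
#' transition, used as the minimum age for division.  Returns `+Inf` for
#' quiescent conditions (second branch at `c <= c_cr`): a representable
#' "never divides" sentinel.
#'
#' @param c Oxygen concentration (uM); vectorised.
#' @param params A [cellcycle_params()] object.
#' @param p6p3 Enzyme momenta ratio; selects the branch.
#' @return Age(s) in minutes, possibly `Inf`.
#' @export
age_g1s <- function(c, params, p6p3 = 1) {
  if (any(c < 0)) stop("oxygen concentration must be non-negative")
  if (p6p3 > params$r_cr) {
    params$a_plus * exp(-c / params$c0)
  } else {
    ccr <- critical_oxygen(p6p3, params$ccr)
    out <- rep(Inf, length(c))
    up <- c > ccr
    out[up] <- params$a_minus * (c[up] / ccr - 1)^(-params$beta)
    out
  }
}

#' Age-dependent birth rate
#'
#' Cells younger than the G1/S age cannot divide; cells at or beyond it
#' divide at constant rate `1/tau_p`.  The boundary `a == a_g1s` counts as
#' past the threshold (closed threshold), which makes the crossing-time
#' bookkeeping of the exact simulator unambiguous.
#'
#' @param a Age (minutes); vectorised.
#' @param a_g1s Threshold age (minutes), possibly `Inf`.
#' @param tau_p Post-threshold mean division waiting time (minutes).
#' @return Birth rate(s), per minute.
#' @export
birth_rate_age <- function(a, a_g1s, tau_p) {
  if (any(a < 0)) stop("age must be non-negative")
  ifelse(a >= a_g1s, 1 / tau_p, 0)
}

#' Calibrate the G1/S age law to a target equilibrium oxygen
#'
#' Rescales the active branch prefactor (`a_plus` or `a_minus`) so that
#' `a_G1S(c_inf_target)` equals `-log((tau_p*nu + 1)/2)/nu`, the age at
#' which the Euler-Lotka growth rate vanishes.  This pins the simulated
#' equilibrium (and through it the carrying capacity) regardless of the
#' placeholder constants.
#'
#' @param params A [cellcycle_params()] object.
#' @param c_inf_target Desired equilibrium oxygen (uM).
#' @param p6p3 Enzyme momenta ratio.
#' @param nu Death rate (per minute).
#' @param tau_p Division waiting time (minutes).
#' @return The calibrated `cellcycle_params`.
#' @export
calibrate_cell_cycle <- function(params, c_inf_target, p6p3, nu, tau_p) {
  target <- -log((tau_p * nu + 1) / 2) / nu
  if (!is.finite(target) || target <= 0) {
    stop("calibration target age is not positive (tau_p * nu >= 1?)")
  }
  if (c_inf_target <= 0) stop("`c_inf_target` must be positive")
  if (p6p3 > params$r_cr) {
    params$a_plus <- target * exp(c_inf_target / params$c0)
  } else {
    ccr <- critical_oxygen(p6p3, params$ccr)
    if (c_inf_target <= ccr) {
      stop("target unreachable: c_inf_target is at or below the ",
           "quiescence threshold c_cr = ", signif(ccr, 6))
    }
    params$a_minus <- target * (c_inf_target / ccr - 1)^params$beta
  }
  params
}
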