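#' Quasi-steady oxygen profile
#'
#' Oxygen diffuses and reacts much faster than the cells move or divide, so
#' on population time scales its profile is the solution of the stationary
#' balance
#' \deqn{0 = D_c c'' - (k N(x) + k_2) c + S,}
#' discretised with second-order central differences and no-flux (mirror)
#' boundaries and solved as a tridiagonal system.  For `k2 > 0` the system
#' matrix is an M-matrix, so the solution is strictly positive and bounded
#' by `S/k2`.
#'
#' @param N Per-compartment population (length `N_L`).
#' @param p A [wave_params()] object.
#' @param S Optional per-compartment supply vector (uM/s); defaults to the
#'   constant `p$S_rate`.
#' @return Oxygen concentrations (uM), length `N_L`.
#' @export
oxygen_quasi_steady <- function(N, p, S = NULL) {
  validate_wave_params(p)
  if (any(N < 0)) stop("populations must be non-negative")
  er <- engine_rates(p)
  if (is.null(S)) S <- rep(p$S_rate, length(N))
  stopifnot(length(S) == length(N))
  .ox_quasi_steady_cpp(as.numeric(N), er$Dch2, er$kox, er$k2, 60 * S)
}

#' Explicit time stepping of the oxygen PDE
#'
#' Advances `dc/dt = D_c c'' - k c N - k2 c + S` by explicit Euler (default)
#' or classic four-stage Runge-Kutta with no-flux boundaries, holding the
#' population frozen (operator splitting).  The substep is checked against
#' the diffusive stability bound `0.9 * h^2 / (2 D_c)`.
#'
#' @param c0 Initial oxygen (uM), length `N_L`.
#' @param N Per-compartment population, frozen during the step.
#' @param p A [wave_params()] object.
#' @param dt Time to advance (minutes).
#' @param method `"euler"` or `"rk4"`.
#' @param nsub Number of substeps; `dt/nsub` must satisfy the bound.
#' @param S Optional supply vector (uM/s).
#' @return Updated oxygen concentrations (uM).
#' @export
oxygen_step <- function(c0, N, p, dt, method = c("euler", "rk4"), nsub = 1,
                        S = NULL) {
  validate_wave_params(p)
  method <- match.arg(method)
  er <- engine_rates(p)
  bound <- 0.9 / (2 * er$Dch2)    # minutes
  if (dt / nsub > bound) {
    stop(sprintf("substep %.3g min exceeds the stability bound %.3g min; increase `nsub`",
                 dt / nsub, bound))
  }
  if (is.null(S)) S <- rep(p$S_rate, length(N))
  .ox_step_cpp(as.numeric(c0), as.numeric(N), er$Dch2, er$kox, er$k2,
               60 * S, dt, as.integer(nsub),
               if (method == "euler") 0L else 1L)
}
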