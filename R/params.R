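#' Model parameters
#'
#' Bundles every rate, diffusivity and lattice property of the multi-scale
#' growth model.  Units follow the conventions the parameters are usually
#' quoted in: per-minute rates for the population dynamics, per-second rates
#' for the (much faster) oxygen dynamics, millimetres for space and
#' micromolar for oxygen.  Internally all simulators convert to a single
#' per-minute, lattice-unit system.
#'
#' @param nu Death rate (per minute).
#' @param tau_p Mean waiting time between passing the G1/S transition and
#'   dividing (minutes); the post-threshold division rate is `1/tau_p`.
#' @param D_c Oxygen diffusivity (mm^2/s).
#' @param D_n Cell diffusivity (mm^2/s).
#' @param k Per-cell oxygen consumption rate (per second).
#' @param k2 Background oxygen decay rate (per second).  Defaults to
#'   `S_rate / c_scale`, so that the oxygen level ahead of the front,
#'   `S_rate / k2`, equals the characteristic scale `c_scale`.
#' @param S_rate Oxygen supply rate (uM/s).
#' @param c_scale Characteristic oxygen concentration used for
#'   nondimensionalisation (uM).
#' @param h Lattice spacing (mm).  Not a quantity with a canonical literature
#'   value; 0.1 mm (a few cell diameters) is the default.
#' @param N_L Number of lattice compartments (>= 3).
#' @param theta Interface threshold for the hybrid scheme (cells).
#' @param p6p3 Ratio of the SCF-regulating enzyme momenta p6/p3
#'   (dimensionless); selects the branch of the G1/S age law.
#' @param cellcycle A [cellcycle_params()] object; by default one whose
#'   exponential-branch oxygen scale `c0` equals `c_scale`, so the model has
#'   a single characteristic oxygen concentration.
#' @param seed Optional default RNG seed recorded with the parameters.
#'
#' @return An object of class `wave_params` (a named list).
#' @examples
#' p <- wave_params()
#' dimensionless_groups(p)
#' @export
wave_params <- function(nu = 0.0000416667, tau_p = 480,
                        D_c = 1e-3, D_n = 1e-7,
                        k = 1.57e-4, k2 = NULL, S_rate = 1.57e-2,
                        c_scale = 1, h = 0.1, N_L = 80, theta = 300,
                        p6p3 = 1, cellcycle = NULL,
                        seed = NULL) {
  if (is.null(k2)) k2 <- S_rate / c_scale
  if (is.null(cellcycle)) cellcycle <- cellcycle_params(c0 = c_scale)
  p <- structure(list(
    nu = nu, tau_p = tau_p, D_c = D_c, D_n = D_n, k = k, k2 = k2,
    S_rate = S_rate, c_scale = c_scale, h = h, N_L = as.integer(N_L),
    theta = theta, p6p3 = p6p3, cellcycle = cellcycle, seed = seed
  ), class = "wave_params")
  validate_wave_params(p)
  p
}

validate_wave_params <- function(p) {
  pos <- c("nu", "tau_p", "D_c", "D_n", "k", "k2", "S_rate", "c_scale", "h")
  for (f in pos) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", f, "` must be a single positive finite number", call. = FALSE)
    }
  }
  if (p$N_L < 3L) stop("`N_L` must be at least 3", call. = FALSE)
  if (p$theta < 1) stop("`theta` must be at least 1", call. = FALSE)
  invisible(p)
}

#' @export
print.wave_params <- function(x, ...) {
  cat("<wave_params>\n")
  cat(sprintf("  nu = %g /min, tau_p = %g min\n", x$nu, x$tau_p))
  cat(sprintf("  D_c = %g, D_n = %g mm^2/s; h = %g mm, N_L = %d\n",
              x$D_c, x$D_n, x$h, x$N_L))
  cat(sprintf("  k = %g /s, k2 = %g /s, S = %g uM/s, c_scale = %g uM\n",
              x$k, x$k2, x$S_rate, x$c_scale))
  cat(sprintf("  theta = %g cells, p6/p3 = %g\n", x$theta, x$p6p3))
  invisible(x)
}

# internal: per-minute, lattice-unit rates used by all engines
engine_rates <- function(p) {
  list(
    d    = 60 * p$D_n / p$h^2,   # cell hop rate per neighbour, /min
    Dch2 = 60 * p$D_c / p$h^2,   # oxygen diffusion, /min
    kox  = 60 * p$k,             # consumption, /min/cell
    k2   = 60 * p$k2,            # decay, /min
    S    = 60 * p$S_rate,        # supply, uM/min
    b    = 1 / p$tau_p,          # post-G1/S division rate, /min
    nu   = p$nu
  )
}

#' Dimensionless groups of the model
#'
#' Computes the small parameters that control the separation of time scales:
#' `eps1 = tau_c * nu`, `eps2 = tau_c / tau_n = D_n / D_c`, the dimensionless
#' consumption `kappa = tau_c * k`, decay `kappa2 = tau_c * k2`, and supply
#' `S_tilde = tau_c * S / c_scale`, where `tau_c = h^2/D_c` and
#' `tau_n = h^2/D_n` are the oxygen and cell diffusion times across one
#' compartment.  The coarse-grained and hybrid descriptions assume
#' `eps1 << 1`, `eps2 << 1` and `eps2 << eps1`.
#'
#' @param p A [wave_params()] object.
#' @return A one-row tibble with the groups, the derived time scales
#'   (seconds) and logical validity flags.
#' @export
dimensionless_groups <- function(p) {
  validate_wave_params(p)
  tau_c <- p$h^2 / p$D_c            # seconds
  tau_n <- p$h^2 / p$D_n
  nu_s <- p$nu / 60                 # per second
  eps1 <- tau_c * nu_s
  eps2 <- tau_c / tau_n
  tibble::tibble(
    eps1 = eps1, eps2 = eps2,
    kappa = tau_c * p$k, kappa2 = tau_c * p$k2,
    S_tilde = tau_c * p$S_rate / p$c_scale,
    tau_c = tau_c, tau_n = tau_n,
    eps1_small = eps1 < 0.1, eps2_small = eps2 < 0.1,
    eps2_ll_eps1 = eps2 < eps1,
    valid = eps1 < 0.1 & eps2 < 0.1 & eps2 < eps1
  )
}

#' Report on the ordering of the model's time scales
#'
#' The coarse-graining requires `tau_n >> 1/nu >> tau_c`: cells must live much
#' longer than oxygen takes to equilibrate across a compartment, and move
#' much more slowly than they turn over.  This function reports the three
#' time scales and whether each inequality holds with margin `margin`; it
#' never throws, so any parameter regime can still be simulated.
#'
#' @param p A [wave_params()] object.
#' @param margin Required ratio between consecutive scales (default 10).
#' @return A one-row tibble with `tau_c`, `nu_inv`, `tau_n` (seconds), the
#'   two flags and `ordering_ok`.
#' @export
check_timescales <- function(p, margin = 10) {
  validate_wave_params(p)
  tau_c <- p$h^2 / p$D_c
  tau_n <- p$h^2 / p$D_n
  nu_inv <- 60 / p$nu              # seconds
  f1 <- tau_n / nu_inv > margin    # tau_n >> 1/nu
  f2 <- nu_inv / tau_c > margin    # 1/nu >> tau_c
  tibble::tibble(tau_c = tau_c, nu_inv = nu_inv, tau_n = tau_n,
                 margin = margin,
                 tau_n_gg_nu_inv = f1, nu_inv_gg_tau_c = f2,
                 ordering_ok = f1 & f2)
}

#' Equilibrium oxygen concentration
#'
#' Solves for the oxygen level `c_inf` at which the population neither grows
#' nor decays: the dimensionless G1/S age must satisfy
#' `nu * a_G1S(c_inf) = -log((tau_p * nu + 1)/2)` (natural logarithm), which
#' is equivalent to the Euler-Lotka growth rate vanishing.  Root-finding is
#' by safeguarded bisection to relative tolerance 1e-10.
#'
#' @param p A [wave_params()] object.
#' @param lower,upper Search bracket for `c_inf` (uM).
#' @return `c_inf` in uM.
#' @export
equilibrium_oxygen <- function(p, lower = 1e-9, upper = NULL) {
  validate_wave_params(p)
  target <- -log((p$tau_p * p$nu + 1) / 2) / p$nu  # minutes
  if (target <= 0) stop("tau_p * nu >= 1: no positive-growth equilibrium exists")
  if (is.null(upper)) upper <- 1e3 * p$c_scale
  f <- function(cc) age_g1s(cc, p$cellcycle, p$p6p3) - target
  flo <- f(lower); fhi <- f(upper)
  if (!is.finite(flo)) flo <- Inf  # quiescent at low oxygen: age is +Inf
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    stop("calibration error: nu * a_G1S(c) - target does not change sign on the bracket")
  }
  r <- uniroot(f, c(lower, upper), tol = 1e-12 * upper, maxiter = 2000)
  cinf <- r$root
  # polish to relative tolerance 1e-10 by bisection on the exact condition
  lo <- max(lower, cinf * (1 - 1e-6)); hi <- min(upper, cinf * (1 + 1e-6))
  if (f(lo) * f(hi) < 0) {
    while ((hi - lo) > 1e-11 * hi) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    }
    cinf <- (lo + hi) / 2
  }
  cinf
}

#' Carrying capacity of a compartment
#'
#' At the equilibrium oxygen level the supply balances consumption, giving
#' `K = S_rate / (k * c_inf)` cells per compartment.  The value is returned
#' as a positive real; consumers decide how to round.  (The realised
#' mean-field plateau behind a front is `K - k2/k`, slightly below `K`,
#' because the background decay `k2 * c` also consumes oxygen.)
#'
#' @param p A [wave_params()] object.
#' @param c_inf Equilibrium oxygen (uM), e.g. from [equilibrium_oxygen()].
#' @return Carrying capacity (cells per compartment).
#' @export
carrying_capacity <- function(p, c_inf) {
  validate_wave_params(p)
  if (!is.numeric(c_inf) || c_inf <= 0) stop("`c_inf` must be positive")
  p$S_rate / (p$k * c_inf)
}
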