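#' Euler-Lotka growth rate at fixed oxygen
#'
#' The asymptotic exponential growth rate of the age-structured population at
#' a fixed G1/S threshold age is the unique real root of the renewal
#' (Euler-Lotka) identity
#' \deqn{2 b e^{-(\lambda+\nu)A} = \lambda + \nu + b,}
#' where `b = 1/tau_p` is the post-threshold division rate, `nu` the death
#' rate and `A = a_g1s` the threshold age.  All quantities are in minutes;
#' use [lambda_dimensionless()] for the rescaled representation.  The root is
#' found by safeguarded bisection on the analytic bracket
#' `[-nu, 1/tau_p - nu]`, exact for the degenerate cases `A = 0`
#' (`lambda = 1/tau_p - nu`) and `A = Inf` (`lambda = -nu`, pure death).
#'
#' @param a_g1s Threshold age (minutes), in `[0, Inf]`.
#' @param nu Death rate (per minute).
#' @param tau_p Division waiting time (minutes).
#' @return An object of class `growth_rate` with fields `lambda` (per
#'   minute), `a_g1s`, `nu`, `b`, `residual` and `bracket`.
#' @examples
#' growth_rate(0, nu = 0.0000416667, tau_p = 480)$lambda  # 1/480 - nu
#' @export
growth_rate <- function(a_g1s, nu, tau_p) {
  stopifnot(length(a_g1s) == 1L, a_g1s >= 0, nu > 0, tau_p > 0)
  b <- 1 / tau_p
  g <- function(l) 2 * b * exp(-(l + nu) * a_g1s) - (l + nu + b)
  if (!is.finite(a_g1s)) {
    lam <- -nu
  } else if (a_g1s == 0) {
    lam <- b - nu
  } else {
    lo <- -nu; hi <- b - nu
    # g(lo) = b > 0, g(hi) <= 0; plain bisection is robust here
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-16 * (1 + abs(mid))) break
    }
    lam <- (lo + hi) / 2
  }
  res <- if (is.finite(a_g1s)) g(lam) else 0
  structure(list(lambda = lam, a_g1s = a_g1s, nu = nu, b = b,
                 residual = res, bracket = c(-nu, b - nu)),
            class = "growth_rate")
}

#' @export
print.growth_rate <- function(x, ...) {
  cat(sprintf("<growth_rate> lambda = %.8g /min (a_G1S = %g min, residual %.2e)\n",
              x$lambda, x$a_g1s, x$residual))
  invisible(x)
}

#' @rdname growth_rate
#' @param x A `growth_rate` object.
#' @param ... Unused.
#' @method tidy growth_rate
#' @export
tidy.growth_rate <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, a_g1s = x$a_g1s, nu = x$nu, b = x$b,
                 residual = x$residual)
}

#' Growth rate of a spatial Fourier mode
#'
#' With no-flux boundaries the diffusion operator contributes eigenvalues
#' `-D * k^2 * pi^2 / L^2`, so mode `k` grows at
#' `lambda_k = lambda_0 - D k^2 pi^2 / L^2`.  In the fully rescaled
#' (dimensionless) representation the cell diffusivity is 1 and `L` is in
#' lattice units; pass `D` explicitly to work in other unit systems.
#'
#' @param sol A [growth_rate()] object (or a bare growth rate).
#' @param k Mode number (non-negative integer).
#' @param L Domain length (same spatial units as `D`).
#' @param D Diffusivity (default 1: the dimensionless convention).
#' @return The mode growth rate, same time units as `sol`.
#' @export
mode_growth_rate <- function(sol, k, L, D = 1) {
  stopifnot(k >= 0, k == round(k), L > 0)
  lam <- if (inherits(sol, "growth_rate")) sol$lambda else sol
  lam - D * k^2 * pi^2 / L^2
}

#' Convert a per-minute growth rate to the rescaled time variable
#'
#' The coarse-grained analysis uses the slow time `sigma` in which the cell
#' diffusion time across one compartment is 1; a per-minute rate converts by
#' multiplication with `tau_n = h^2 / D_n` (in minutes).  Similarly an age in
#' minutes maps to the rescaled age `gamma = a / tau_n`, so that
#' `nu * a = (eps1/eps2) * gamma`.
#'
#' @param lambda_per_min Rate in per-minute units.
#' @param p A [wave_params()] object.
#' @return Rate in rescaled (sigma) units.
#' @export
lambda_dimensionless <- function(lambda_per_min, p) {
  tau_n_min <- p$h^2 / p$D_n / 60
  lambda_per_min * tau_n_min
}

#' Equilibrium age distribution
#'
#' In a population growing exponentially at rate `lambda` the stable age
#' profile is piecewise exponential: density proportional to
#' `exp(-r1 a)` below the threshold age `A` and to
#' `exp(-r1 A - r2 (a - A))` above it, with `r1 = lambda + nu` and
#' `r2 = lambda + nu + b`.  The density is continuous at `A` and its
#' normalisation is available in closed form.
#'
#' @param sol A [growth_rate()] object.
#' @return An object of class `eq_age_dist` with fields `r1`, `r2`, `A`,
#'   the partial masses `Z1` (below `A`), `Z2` (above) and `Z = Z1 + Z2`.
#' @export
equilibrium_age_distribution <- function(sol) {
  stopifnot(inherits(sol, "growth_rate"))
  A <- sol$a_g1s
  r1 <- sol$lambda + sol$nu
  r2 <- sol$lambda + sol$nu + sol$b
  if (r2 <= 0) stop("non-normalisable equilibrium age distribution (r2 <= 0)")
  if (r1 <= 0) stop("non-normalisable equilibrium age distribution (r1 <= 0)")
  if (is.finite(A)) {
    Z1 <- -expm1(-r1 * A) / r1
    Z2 <- exp(-r1 * A) / r2
  } else {
    Z1 <- 1 / r1
    Z2 <- 0
  }
  structure(list(r1 = r1, r2 = r2, A = A, Z1 = Z1, Z2 = Z2, Z = Z1 + Z2,
                 b = sol$b, nu = sol$nu, lambda = sol$lambda),
            class = "eq_age_dist")
}

#' @rdname equilibrium_age_distribution
#' @param x Ages (minutes).
#' @param dist An `eq_age_dist` object.
#' @export
deq_age <- function(x, dist) {
  d <- numeric(length(x))
  lo <- x >= 0 & x < dist$A
  hi <- x >= dist$A
  d[lo] <- exp(-dist$r1 * x[lo]) / dist$Z
  d[hi] <- exp(-dist$r1 * dist$A - dist$r2 * (x[hi] - dist$A)) / dist$Z
  d
}

#' @rdname equilibrium_age_distribution
#' @export
peq_age <- function(x, dist) {
  p <- numeric(length(x))
  lo <- x >= 0 & x < dist$A
  hi <- x >= dist$A
  p[lo] <- -expm1(-dist$r1 * x[lo]) / dist$r1 / dist$Z
  p[hi] <- (dist$Z1 + (exp(-dist$r1 * dist$A) / dist$r2) *
              (-expm1(-dist$r2 * (x[hi] - dist$A)))) / dist$Z
  p
}

#' @rdname equilibrium_age_distribution
#' @param q Probabilities in `[0, 1]`.
#' @export
qeq_age <- function(q, dist) {
  stopifnot(all(q >= 0 & q <= 1))
  out <- numeric(length(q))
  uz <- q * dist$Z
  lo <- uz < dist$Z1 | dist$Z2 == 0
  out[lo] <- -log1p(-uz[lo] * dist$r1) / dist$r1
  if (any(!lo)) {
    w <- (1 - q[!lo]) * dist$Z
    out[!lo] <- dist$A + (log(dist$Z2) - log(w)) / dist$r2
  }
  out
}

#' @rdname equilibrium_age_distribution
#' @param n Number of draws.
#' @export
req_age <- function(n, dist) qeq_age(runif(n), dist)

#' Equilibrium mass fraction beyond the G1/S threshold
#'
#' @param dist An `eq_age_dist` object.
#' @return The probability that an equilibrium-age cell is older than the
#'   threshold, `Z2 / (Z1 + Z2)`.
#' @export
mass_fraction_above <- function(dist) dist$Z2 / dist$Z

#' Equilibrium (coarse-grained) birth rate
#'
#' The birth rate of a population whose age distribution is at equilibrium:
#' division rate times the equilibrium mass fraction beyond the G1/S
#' threshold (the definitional route).  A closed-form expression,
#' `b (lambda+nu) e^{-(lambda+nu)A} / (lambda+nu+b(1-e^{-(lambda+nu)A}))`,
#' is available as `method = "closed_form"`; the two agree to rounding
#' error, and both satisfy the renewal identity `B - nu = lambda` exactly.
#'
#' @param sol A [growth_rate()] object.
#' @param method `"definitional"` (default) or `"closed_form"`.
#' @return Birth rate per minute.
#' @export
equilibrium_birth_rate <- function(sol, method = c("definitional", "closed_form")) {
  method <- match.arg(method)
  if (!is.finite(sol$a_g1s)) return(0)
  if (method == "definitional") {
    dist <- equilibrium_age_distribution(sol)
    sol$b * mass_fraction_above(dist)
  } else {
    r1 <- sol$lambda + sol$nu
    A <- sol$a_g1s
    e <- exp(-r1 * A)
    sol$b * r1 * e / (r1 + sol$b * (1 - e))
  }
}

#' Tabulate oxygen-dependent equilibrium quantities
#'
#' @param c Oxygen grid (uM).
#' @param p A [wave_params()] object.
#' @return A tibble with `c`, `a_g1s`, `lambda`, `B` and
#'   `mass_above` columns, ready for export as delimited text.
#' @export
equilibrium_table <- function(c, p) {
  purrr::map_dfr(c, function(cc) {
    A <- age_g1s(cc, p$cellcycle, p$p6p3)
    sol <- growth_rate(A, p$nu, p$tau_p)
    tibble::tibble(
      c = cc, a_g1s = A, lambda = sol$lambda,
      B = equilibrium_birth_rate(sol),
      mass_above = if (is.finite(A)) {
        mass_fraction_above(equilibrium_age_distribution(sol))
      } else 0
    )
  })
}
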