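# Interface rules of the hybrid scheme, as plain R functions operating on a
# light-weight state (populations + ages).  The compiled engine implements
# the same rules inline; these reference implementations define the rules
# precisely and are what the property tests exercise.

#' Locate the hybrid interface
#'
#' The interface sits in the last (rightmost) compartment whose total
#' population exceeds the threshold `theta`.
#'
#' @param N Per-compartment population (mean-field values may be real).
#' @param theta Threshold (cells).
#' @return The 1-based interface index, or `NA` if no compartment qualifies
#'   (the all-stochastic sentinel).
#' @export
locate_interface <- function(N, theta) {
  if (any(N < 0)) stop("populations must be non-negative")
  idx <- which(N > theta)
  if (length(idx) == 0L) NA_integer_ else max(idx)
}

#' Conservative deterministic flux between the last mean-field compartment
#' and the interface
#'
#' One explicit step of the exchange between the last mean-field compartment
#' and the interface density view: the flux `d * (u[I-1] - u[I])` is applied
#' antisymmetrically (the gain of one side is the loss of the other), so
#' total mass is conserved to rounding error.
#'
#' @param u_mf Population of the last mean-field compartment.
#' @param u_if Interface population (density view, may be fractional).
#' @param d Hop rate `D_n/h^2` (per minute).
#' @param dt Time step (minutes).
#' @return A list with updated `u_mf` and `u_if`.
#' @export
deterministic_fluxes <- function(u_mf, u_if, d, dt) {
  f <- d * (u_mf - u_if)
  list(u_mf = u_mf - dt * f, u_if = u_if + dt * f)
}

#' Renormalise the interface population to an integer
#'
#' The interface's density view accumulates fractional mass from the
#' deterministic fluxes.  The fractional part is resolved probabilistically:
#' with probability equal to the fractional part the count is rounded up
#' (one whole cell is added, with an age drawn from the equilibrium age
#' distribution, and the missing mass is taken evenly from the mean-field
#' compartments); otherwise it is rounded down (the fractional mass is
#' spread evenly over the mean-field compartments).  If rounding removes
#' whole cells, their ages are drawn from the interface's empirical age
#' structure.  Total mass is conserved exactly in every branch and the
#' expected interface population is unchanged.
#'
#' @param u Mean-field populations (vector, possibly empty).
#' @param n_if Integer cell count at the interface.
#' @param frac Fractional ledger of the interface density view
#'   (`u_if = n_if + frac`).
#' @param ages Ages of the interface cells (minutes), length `n_if`.
#' @param dist An [equilibrium_age_distribution()] object for sampled ages.
#' @return A list with `u`, `n_if`, `ages`, `frac` (0 unless the mean-field
#'   domain is empty) and `warned`.
#' @export
renormalize_interface <- function(u, n_if, frac, ages, dist) {
  u_if <- n_if + frac
  warned <- FALSE
  fl <- floor(u_if)
  fr <- u_if - fl
  n_new <- fl + as.integer(runif(1) < fr)
  delta <- n_new - n_if
  if (delta > 0) {
    ages <- c(ages, req_age(delta, dist))
  } else if (delta < 0) {
    drop <- sample.int(length(ages), min(-delta, length(ages)))
    ages <- ages[-drop]
    n_new <- n_if - length(drop)
  }
  mass_adj <- u_if - n_new
  if (length(u) > 0) {
    u <- u + mass_adj / length(u)
    frac <- 0
  } else {
    frac <- mass_adj
    warned <- TRUE
    warning("empty mean-field domain: fractional mass kept in the interface ledger")
  }
  list(u = u, n_if = n_new, ages = ages, frac = frac, warned = warned)
}

#' Relocate the hybrid interface
#'
#' After each update the interface condition is re-checked.  If the
#' interface population dropped to or below `theta`, the interface scans
#' left: each mean-field compartment it passes is converted to a stochastic
#' one (probabilistic rounding of its mass, remainder spread evenly over the
#' remaining mean-field compartments, every cell assigned an equilibrium
#' age), until a compartment satisfying the condition is found or the domain
#' becomes all-stochastic.  Otherwise it scans right while its right
#' neighbour also satisfies the condition, converting former interface
#' compartments to mean-field ones (count becomes density, ages discarded).
#'
#' @param state A list with `u` (mean-field populations), `I` (interface
#'   index, 1-based), `counts` (integer populations of compartments
#'   `I..N_L`), `ages` (list of age vectors for compartments `I..N_L`).
#' @param theta Threshold.
#' @param dist_fun Function of a compartment index returning the
#'   `eq_age_dist` used for age assignment there.
#' @return The updated state; `I = NA` flags all-stochastic.
#' @export
move_interface <- function(state, theta, dist_fun) {
  u <- state$u; I <- state$I
  counts <- state$counts; ages <- state$ages
  if (counts[1] > theta) {
    while (length(counts) > 1 && counts[2] > theta) {
      u <- c(u, counts[1])            # rightward: ages discarded
      counts <- counts[-1]; ages <- ages[-1]
      I <- I + 1
    }
  } else {
    while (counts[1] <= theta) {
      if (length(u) == 0L) { I <- NA_integer_; break }
      val <- u[length(u)]
      u <- u[-length(u)]
      n_new <- floor(val) + as.integer(runif(1) < (val - floor(val)))
      if (length(u) > 0) u <- u + (val - n_new) / length(u)
      I <- I - 1
      counts <- c(n_new, counts)
      ages <- c(list(req_age(n_new, dist_fun(I))), ages)
    }
  }
  list(u = u, I = I, counts = counts, ages = ages)
}
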