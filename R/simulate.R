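# Simulation front-ends.  All four simulators take a scenario, run one or
# more realisations, and return a tidy trajectory tibble with one row per
# (realisation, snapshot time, compartment).

#' Reaction propensities of an age-structured compartment
#'
#' The per-compartment transition rates of the exact simulator: birth
#' `(mature count)/tau_p` (cells at or beyond the G1/S age), death
#' `nu * N`, and diffusion `D_n/h^2 * N` towards each of `z` neighbours.
#'
#' @param ages Cohort ages (minutes).
#' @param counts Cohort sizes (cells), same length as `ages`.
#' @param a_g1s Local G1/S threshold age (minutes).
#' @param p A [wave_params()] object.
#' @param z Number of lattice neighbours (2 interior, 1 boundary).
#' @return A one-row tibble with `birth`, `death`, `diffusion` (total over
#'   neighbours) and `total`, all per minute.
#' @export
compartment_propensities <- function(ages, counts, a_g1s, p, z = 2) {
  stopifnot(length(ages) == length(counts), all(counts >= 1))
  er <- engine_rates(p)
  N <- sum(counts)
  mature <- sum(counts[ages >= a_g1s])
  tibble::tibble(
    birth = mature * er$b,
    death = er$nu * N,
    diffusion = er$d * N * z,
    total = mature * er$b + er$nu * N + er$d * N * z
  )
}

ox_mode_code <- function(oxygen) {
  switch(match.arg(oxygen, c("quasi", "dynamic", "frozen")),
         quasi = 0L, dynamic = 1L, frozen = 2L)
}

cc_engine_args <- function(p) {
  cc <- p$cellcycle
  branch <- if (p$p6p3 > cc$r_cr) 1L else 2L
  c_cr <- if (branch == 2L) critical_oxygen(p$p6p3, cc$ccr) else 1
  list(branch = branch, a_plus = cc$a_plus, a_minus = cc$a_minus,
       beta = cc$beta, c_cr = c_cr, c0 = cc$c0)
}

realisation_seed <- function(base_seed, k) {
  # counter-based derivation; keeps every derived seed below 2^31
  (as.integer(base_seed) + 99991L * as.integer(k)) %% .Machine$integer.max
}

build_trajectory <- function(raw, scn, realisation, model) {
  NL <- scn$params$N_L
  nt <- length(raw$time)
  region_lab <- c("meanfield", "interface", "stochastic")
  iface <- raw$interface
  tibble::tibble(
    realisation = realisation,
    time = rep(raw$time, times = NL),
    compartment = rep(seq_len(NL), each = nt),
    x_mm = (rep(seq_len(NL), each = nt) - 1) * scn$params$h,
    N = as.vector(raw$N),
    c = as.vector(raw$c),
    mature = if (!is.null(raw$mature)) as.vector(raw$mature) else NA_real_,
    region = if (!is.null(raw$region)) {
      region_lab[as.vector(raw$region) + 1L]
    } else NA_character_,
    interface = if (!is.null(iface)) rep(as.integer(iface) + 1L, times = NL)
                else NA_integer_,
    model = model
  )
}

finish_trajectory <- function(parts, scn, model, extra = list()) {
  out <- dplyr::bind_rows(parts)
  out <- dplyr::arrange(out, .data$realisation, .data$time, .data$compartment)
  attr(out, "scenario_name") <- scn$name
  attr(out, "K") <- scn$K
  attr(out, "model") <- model
  attr(out, "params") <- scn$params
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("wave_trajectory", class(out))
  out
}

run_engine_realisations <- function(scn, mode, theta, realisations, seed,
                                    oxygen, sync_dt, return_state,
                                    debug_mass, model) {
  p <- scn$params
  er <- engine_rates(p)
  cc <- cc_engine_args(p)
  I0 <- if (mode == 1L) {
    li <- locate_interface(scn$N0, theta)
    if (is.na(li)) -1L else li - 1L
  } else -1L
  parts <- vector("list", realisations)
  states <- vector("list", realisations)
  reloc <- vector("list", realisations)
  for (r in seq_len(realisations)) {
    set.seed(realisation_seed(seed, r))
    raw <- .sim_engine_cpp(
      mode, p$N_L, er$d, er$nu, er$b,
      er$Dch2, er$kox, er$k2, rep(er$S, p$N_L),
      ox_mode_code(oxygen), 0.9 / (2 * er$Dch2),
      cc$branch, cc$a_plus, cc$a_minus, cc$beta, cc$c_cr, cc$c0,
      theta, sync_dt, scn$snapshot_times, scn$N0,
      rep(scn$c_inf, p$N_L), I0, return_state, debug_mass)
    parts[[r]] <- build_trajectory(raw, scn, r, model)
    states[[r]] <- raw$state
    reloc[[r]] <- tibble::tibble(realisation = r, time = raw$reloc_time,
                                 from = raw$reloc_from + 1L,
                                 to = raw$reloc_to + 1L)
  }
  finish_trajectory(parts, scn, model,
                    extra = list(states = if (return_state) states else NULL,
                                 relocations = dplyr::bind_rows(reloc),
                                 theta = theta, seed = seed))
}

#' Simulate the full age-structured stochastic model
#'
#' Exact, event-driven simulation of the age-structured
#' birth-death-diffusion process on the lattice.  Between oxygen
#' resynchronisations the G1/S threshold age is frozen per compartment, so
#' the instants at which immature cohorts become eligible to divide are
#' deterministic and the total propensity is piecewise constant; waiting
#' times are drawn by exact inversion of the piecewise-linear integrated
#' hazard (no thinning).  Births remove one mature cell and create a
#' two-cell cohort of age zero; deaths remove a uniformly chosen cell;
#' diffusion moves a uniformly chosen cell to a neighbour, preserving its
#' birth time.
#'
#' @param scn A [scenario()] object.
#' @param realisations Number of independent realisations.
#' @param seed Base seed; realisation `k` runs with a seed derived from it
#'   by a counter scheme, so single realisations are reproducible in
#'   isolation.
#' @param oxygen Oxygen model between syncs: `"quasi"` (quasi-steady solve,
#'   default), `"dynamic"` (explicit stepping) or `"frozen"`.
#' @param sync_dt Oxygen resynchronisation interval (minutes).
#' @param return_state Keep the final age structure of each realisation
#'   (attribute `states`).
#' @param debug_mass Continuously assert the mass ledger (slower).
#' @return A `wave_trajectory` tibble: columns `realisation`, `time`,
#'   `compartment`, `x_mm`, `N`, `c`, `mature`, `region`, `interface`,
#'   `model`.
#' @export
simulate_full <- function(scn, realisations = 1, seed = scn$base_seed,
                          oxygen = "quasi", sync_dt = scn$sync_dt,
                          return_state = FALSE, debug_mass = FALSE) {
  run_engine_realisations(scn, 0L, theta = scn$params$theta,
                          realisations, seed, oxygen, sync_dt,
                          return_state, debug_mass, model = "full")
}

#' Simulate the hybrid mean-field / stochastic model
#'
#' Couples the coarse-grained mean-field PDE (bulk, left of the interface)
#' to the full age-structured stochastic model (front, right of the
#' interface).  The interface is the last compartment whose population
#' exceeds `theta`; it carries both a density view and an age-structured
#' population.  Each iteration: draw and apply the next stochastic event
#' (exact, as in [simulate_full()]), advance the mean-field PDE and the
#' whole-domain oxygen over the elapsed time, renormalise the interface
#' population to an integer (probabilistic rounding, mass exchanged evenly
#' with the mean-field domain), and relocate the interface.  Cells crossing
#' from the mean-field description to the stochastic one receive ages drawn
#' from the equilibrium age distribution.
#'
#' @inheritParams simulate_full
#' @param theta Interface threshold (cells).
#' @return A `wave_trajectory` tibble; attribute `relocations` logs every
#'   interface move.
#' @export
simulate_hybrid <- function(scn, realisations = 1, seed = scn$base_seed,
                            theta = scn$params$theta, oxygen = "quasi",
                            sync_dt = scn$sync_dt, return_state = FALSE,
                            debug_mass = FALSE) {
  run_engine_realisations(scn, 1L, theta, realisations, seed, oxygen,
                          sync_dt, return_state, debug_mass,
                          model = "hybrid")
}

#' Simulate the coarse-grained stochastic model
#'
#' Age-free exact SSA in which each compartment carries only a cell count
#' and the birth propensity is `B(c) * N` with `B` the equilibrium
#' (coarse-grained) birth rate at the local oxygen level, re-evaluated at
#' every oxygen resynchronisation.
#'
#' @inheritParams simulate_full
#' @return A `wave_trajectory` tibble (`mature` is `NA`: the model carries
#'   no age structure).
#' @export
simulate_cg_ssa <- function(scn, realisations = 1, seed = scn$base_seed,
                            oxygen = "quasi", sync_dt = scn$sync_dt) {
  p <- scn$params
  er <- engine_rates(p)
  cc <- cc_engine_args(p)
  parts <- vector("list", realisations)
  for (r in seq_len(realisations)) {
    set.seed(realisation_seed(seed, r))
    raw <- .sim_cg_ssa_cpp(
      p$N_L, er$d, er$nu, er$b, er$Dch2, er$kox, er$k2, rep(er$S, p$N_L),
      ox_mode_code(oxygen), 0.9 / (2 * er$Dch2),
      cc$branch, cc$a_plus, cc$a_minus, cc$beta, cc$c_cr, cc$c0,
      sync_dt, scn$snapshot_times, scn$N0, rep(scn$c_inf, p$N_L))
    parts[[r]] <- build_trajectory(raw, scn, r, "cg-ssa")
  }
  finish_trajectory(parts, scn, "cg-ssa", extra = list(seed = seed))
}

#' Simulate the coarse-grained mean-field model
#'
#' Method-of-lines integration of the reaction-diffusion system
#' `dn/dt = D_n n'' + lambda(c) n` with the Euler-Lotka growth rate as
#' reaction term and quasi-steady (default) or dynamically stepped oxygen.
#' Central differences, no-flux boundaries, explicit Euler or RK4 with an
#' enforced diffusive stability bound.  Densities are real-valued; the
#' carrying capacity emerges from the oxygen feedback alone.
#'
#' @inheritParams simulate_full
#' @param dt Time step (minutes); default
#'   `min(0.45 * h^2 / D_n, snapshot interval)`.
#' @param method `"rk4"` (default) or `"euler"`.
#' @return A `wave_trajectory` tibble with a single "realisation".
#' @export
simulate_cg_meanfield <- function(scn, oxygen = "quasi", dt = NULL,
                                  method = c("rk4", "euler")) {
  method <- match.arg(method)
  p <- scn$params
  er <- engine_rates(p)
  oxm <- match.arg(oxygen, c("quasi", "dynamic", "frozen"))
  stab <- 0.9 / (2 * er$d)
  if (is.null(dt)) dt <- min(stab / 2, diff(scn$snapshot_times[1:2]) / 10, 200)
  if (dt > stab) stop("dt exceeds the diffusive stability bound ", signif(stab, 4))

  NL <- p$N_L
  u <- as.numeric(scn$N0)
  cfield <- rep(scn$c_inf, NL)
  Svec <- rep(er$S, NL)
  lam_cache_c <- rep(NA_real_, NL)
  lam_cache_v <- numeric(NL)

  lam_of_c <- function(cf) {
    stale <- is.na(lam_cache_c) | abs(cf - lam_cache_c) > 1e-12 * p$c_scale
    if (any(stale)) {
      A <- age_g1s(cf[stale], p$cellcycle, p$p6p3)
      lam_cache_v[stale] <<- vapply(A, .lambda_root_cpp, 0, nu = er$nu, b = er$b)
      lam_cache_c[stale] <<- cf[stale]
    }
    lam_cache_v
  }
  lap <- function(v) {
    c(v[2] - v[1], v[-c(1, 2)] - 2 * v[-c(1, NL)] + v[-c(NL - 1, NL)],
      v[NL - 1] - v[NL])
  }
  rhs <- function(v, lam) er$d * lap(v) + lam * v

  times <- scn$snapshot_times
  snapN <- matrix(0, length(times), NL)
  snapC <- matrix(0, length(times), NL)
  t <- 0; isnap <- 1
  repeat {
    while (isnap <= length(times) && times[isnap] <= t + 1e-9) {
      snapN[isnap, ] <- u; snapC[isnap, ] <- cfield
      isnap <- isnap + 1
    }
    if (isnap > length(times)) break
    h_dt <- min(dt, times[isnap] - t)
    if (oxm == "quasi") {
      cfield <- .ox_quasi_steady_cpp(pmax(u, 0), er$Dch2, er$kox, er$k2, Svec)
    } else if (oxm == "dynamic") {
      nsub <- ceiling(h_dt / (0.9 / (2 * er$Dch2)))
      cfield <- .ox_step_cpp(cfield, pmax(u, 0), er$Dch2, er$kox, er$k2,
                             Svec, h_dt, as.integer(nsub), 0L)
    }
    lam <- lam_of_c(cfield)
    if (method == "euler") {
      u <- u + h_dt * rhs(u, lam)
    } else {
      k1 <- rhs(u, lam)
      k2 <- rhs(u + h_dt / 2 * k1, lam)
      k3 <- rhs(u + h_dt / 2 * k2, lam)
      k4 <- rhs(u + h_dt * k3, lam)
      u <- u + h_dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (any(u < -1e-6 * max(abs(u)))) {
      stop("mean-field instability: negative densities at t = ", signif(t, 6),
           "; reduce `dt`")
    }
    u[u < 0] <- 0
    t <- t + h_dt
  }
  raw <- list(time = times, N = snapN, c = snapC)
  finish_trajectory(list(build_trajectory(raw, scn, 1L, "cg-mf")),
                    scn, "cg-mf")
}

#' Write / read a trajectory as delimited text
#'
#' Canonical CSV with one row per (realisation, time, compartment); the
#' column dictionary matches the tibble returned by the simulators.
#'
#' @param traj A `wave_trajectory`.
#' @param path Output file path.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tibble::as_tibble(read.csv(path))
}
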