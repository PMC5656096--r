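# Shared fixtures and independent oracles for the test suite.

# Fast-turnover parameter set for stochastic tests (death every 500 min,
# division wait 100 min): keeps event counts small while exercising every
# code path.
fast_params <- function(...) {
  args <- utils::modifyList(
    list(nu = 2e-3, tau_p = 100, D_c = 1e-3, D_n = 1e-7,
         k = 1.57e-4, S_rate = 1.57e-2, c_scale = 1, h = 0.1,
         N_L = 5, theta = 10),
    list(...))
  do.call(wave_params, args)
}

# Cell-cycle parameters on the quiescence branch with a critical oxygen of
# 10 uM: below it a_G1S is infinite, so no cell ever divides.  (Merely making
# a_plus huge does NOT suppress division: equilibrium ages scale with the
# threshold age, so oxygen gradients can still mature cells.)
quiescent_cellcycle <- function() {
  cellcycle_params(r_cr = 2,
                   ccr = list(a0 = 0.1, a1 = exp(-9), a2 = 0, a3 = 1,
                              d1 = 1, d2 = 1, beta1 = 1, e2f_t = 1, H0 = 1))
}

# Fabricate a scenario object around arbitrary parameters / initial data so
# engines can be exercised outside the named scenarios.
make_scn <- function(params, N0, duration, snapshot_dt, c_init,
                     K = NULL, n_real = 1L, base_seed = 1L, sync_dt = 25) {
  stopifnot(length(N0) == params$N_L)
  structure(list(
    name = "custom", params = params, c_inf = c_init,
    K = if (is.null(K)) max(N0) else K, N0 = N0,
    front_index = max(which(N0 > 0), 1L), duration = duration,
    snapshot_times = seq(0, duration, by = snapshot_dt),
    n_real = as.integer(n_real), base_seed = as.integer(base_seed),
    sync_dt = sync_dt
  ), class = "wave_scenario")
}

# Independent oracle: explicit age-discretised integration of the linear
# age-structured dynamics (transport in age, death nu, division b past A,
# newborns at age 0 with factor 2).  Exact along characteristics; births use
# a predictor-corrector (trapezoidal) quadrature.  Returns the measured
# log-slope of total population and the late-time age profile.
bf_age_dynamics <- function(nu, b, A, dt = 0.1, amax = 1500, T = 4000,
                            n0 = NULL) {
  nb <- ceiling(amax / dt)
  ages <- (seq_len(nb) - 1) * dt
  mature <- ages >= A
  surv <- exp(-(nu + b * mature) * dt)
  n <- if (is.null(n0)) rep(1, nb) else n0
  nstep <- ceiling(T / dt)
  logN <- numeric(nstep)
  for (s in seq_len(nstep)) {
    M0 <- sum(n[mature])
    ntr <- c(0, (n * surv)[-nb])
    M1 <- sum(ntr[mature])
    ntr[1] <- 2 * b * dt * (M0 + M1) / 2
    n <- ntr
    logN[s] <- log(sum(n))
  }
  # regress over the last quarter to average out generation-cycle ripples
  keep <- seq(floor(0.75 * nstep), nstep)
  tt <- keep * dt
  lambda_est <- unname(coef(lm(logN[keep] ~ tt))[2])
  list(lambda = lambda_est, ages = ages, profile = n / sum(n) / dt)
}

# Richardson extrapolation of the (first-order accurate) dynamics oracle.
bf_growth_rate <- function(nu, b, A, dt = 1, amax = 3000, T = NULL) {
  if (is.null(T)) T <- 2500 + 10 * A
  l1 <- bf_age_dynamics(nu, b, A, dt = dt, amax = amax, T = T)$lambda
  l2 <- bf_age_dynamics(nu, b, A, dt = dt / 2, amax = amax, T = T)$lambda
  2 * l2 - l1
}

# Independent oracle: thinning sampler for the first event time of a
# process with piecewise-constant intensity `levels` on intervals between
# `breaks`; returns Inf when no event occurs before the final break.
thinning_time <- function(breaks, levels) {
  t <- breaks[1]
  horizon <- breaks[length(breaks)]
  amax <- max(levels)
  repeat {
    t <- t + rexp(1, amax)
    if (t >= horizon) return(Inf)
    lev <- levels[findInterval(t, breaks, rightmost.closed = TRUE)]
    if (runif(1) < lev / amax) return(t)
  }
}

# Total population per snapshot time of a single-realisation trajectory.
total_by_time <- function(traj) {
  out <- dplyr::summarise(dplyr::group_by(traj, .data$realisation, .data$time),
                          N = sum(.data$N), .groups = "drop")
  out
}
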