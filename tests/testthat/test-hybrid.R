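test_that("interface location follows the last-compartment-above-threshold rule", {
  expect_equal(locate_interface(c(5000, 3000, 1500, 200, 0), 2000), 2)
  expect_true(is.na(locate_interface(c(10, 20, 5), 2000)))
  expect_equal(locate_interface(c(5000, 4000, 3000), 2000), 3)
  expect_error(locate_interface(c(-1, 5), 10), "non-negative")
})

test_that("deterministic interface fluxes are antisymmetric and conservative", {
  out <- deterministic_fluxes(400, 400, d = 6e-4, dt = 10)
  expect_equal(out$u_mf, 400); expect_equal(out$u_if, 400)
  out2 <- deterministic_fluxes(480, 310.4, d = 6e-4, dt = 25)
  expect_equal(out2$u_mf + out2$u_if, 480 + 310.4, tolerance = 1e-12)
  expect_lt(out2$u_mf, 480)   # flux runs down the gradient
  expect_gt(out2$u_if, 310.4)
})

test_that("interface renormalisation is an unbiased, conservative rounding", {
  dist <- equilibrium_age_distribution(growth_rate(150, 2e-3, 100))
  u <- c(400, 400, 400)
  # f = 0: no-op
  out <- renormalize_interface(u, 300, 0, ages = rep(50, 300), dist = dist)
  expect_equal(out$n_if, 300); expect_equal(out$u, u)
  # f = 0.7: Bernoulli(0.7) round-up, mass conserved exactly in both branches
  set.seed(31)
  added <- replicate(4000, {
    r <- renormalize_interface(u, 300, 0.7, ages = rep(50, 300), dist = dist)
    expect_equal(sum(r$u) + r$n_if, sum(u) + 300.7, tolerance = 1e-9)
    r$n_if - 300
  })
  se <- sqrt(0.7 * 0.3 / 4000)
  expect_lt(abs(mean(added) - 0.7), 3 * se)
  # negative ledger: removal draws from the interface's empirical ages
  set.seed(32)
  r2 <- renormalize_interface(u, 300, -1.4, ages = rep(50, 300), dist = dist)
  expect_true(r2$n_if %in% c(298, 299))
  expect_equal(sum(r2$u) + r2$n_if, sum(u) + 298.6, tolerance = 1e-9)
  expect_equal(length(r2$ages), r2$n_if)
})

test_that("interface relocation follows the scan rules", {
  dist_fun <- function(i) equilibrium_age_distribution(growth_rate(150, 2e-3, 100))
  # rule trace: profile [5000, 4000, 3000, 100], interface at the 4000
  # compartment (the 3000's left neighbour): moves right onto the 3000
  st <- list(u = c(5000), I = 2,
             counts = c(4000, 3000, 100),
             ages = list(rep(10, 4000), rep(10, 3000), rep(5, 100)))
  out <- move_interface(st, theta = 2000, dist_fun)
  expect_equal(out$I, 3)
  expect_equal(out$u, c(5000, 4000))
  expect_equal(out$counts, c(3000, 100))
  # condition holds at I but fails at I+1: no move
  st2 <- list(u = c(5000), I = 2, counts = c(2500, 150),
              ages = list(rep(1, 2500), rep(1, 150)))
  out2 <- move_interface(st2, theta = 2000, dist_fun)
  expect_equal(out2$I, 2)
  # leftward conversion conserves mass in expectation and assigns ages
  set.seed(41)
  masses <- replicate(3000, {
    st3 <- list(u = c(450.6, 420.3), I = 3, counts = c(120),
                ages = list(rep(30, 120)))
    o <- move_interface(st3, theta = 300, dist_fun)
    expect_equal(o$I, 2)
    expect_equal(length(o$ages[[1]]), o$counts[1])
    sum(o$u) + sum(o$counts)
  })
  expect_equal(mean(masses), 450.6 + 420.3 + 120,
               tolerance = 4 * sd(masses) / sqrt(3000) / 1000 + 1e-3)
  # exhausting the mean-field domain yields the all-stochastic sentinel
  st4 <- list(u = numeric(0), I = 1, counts = c(10), ages = list(rep(1, 10)))
  expect_true(is.na(move_interface(st4, theta = 300, dist_fun)$I))
})

test_that("hybrid with an unreachable threshold reproduces the full SSA exactly", {
  scn <- scenario("paper-wave-small", duration = 6000, snapshot_dt = 1200)
  tf <- simulate_full(scn, realisations = 2, seed = 17)
  th <- simulate_hybrid(scn, realisations = 2, seed = 17, theta = 1e9)
  expect_identical(th$N, tf$N)
  expect_identical(th$c, tf$c)
  expect_identical(th$mature, tf$mature)
})

test_that("hybrid conserves mass exactly when birth and death are negligible", {
  p <- fast_params(nu = 1e-12, D_n = 4e-6, N_L = 12, theta = 50)
  p$cellcycle <- quiescent_cellcycle()
  N0 <- c(rep(400, 6), rep(0, 6))
  scn <- make_scn(p, N0, duration = 5000, snapshot_dt = 500, c_init = 1)
  tr <- simulate_hybrid(scn, seed = 5, theta = 50)
  tot <- total_by_time(tr)
  # the only mass change is the mean-field death reaction at nu = 1e-12
  expect_equal(tot$N, rep(2400, nrow(tot)), tolerance = 1e-8)
})

test_that("the continuous mass-ledger assertion holds on a wave segment", {
  scn <- scenario("paper-wave-small", duration = 4000, snapshot_dt = 2000)
  expect_no_error(simulate_hybrid(scn, realisations = 1, seed = 9,
                                  debug_mass = TRUE))
})

test_that("a bulk-dominated hybrid matches the mean-field PDE", {
  # every compartment above threshold: only the rightmost voxel is
  # stochastic and the rest evolves as the coarse-grained PDE
  scn0 <- scenario("paper-wave-small")
  p <- scn0$params
  Nstar <- (p$S_rate - p$k2 * scn0$c_inf) / (p$k * scn0$c_inf)
  N0 <- Nstar * (1 + 0.04 * sin(seq_len(p$N_L) / 4))
  scn <- make_scn(p, N0, duration = 8000, snapshot_dt = 2000,
                  c_init = scn0$c_inf, K = scn0$K)
  th <- simulate_hybrid(scn, seed = 13, theta = 1)
  tm <- simulate_cg_meanfield(scn)
  iface <- p$N_L
  sel_h <- th$time == 8000 & th$compartment < iface
  sel_m <- tm$time == 8000 & tm$compartment < iface
  expect_equal(unique(th$interface[th$time == 8000]), iface)
  rel <- abs(th$N[sel_h] - tm$N[sel_m]) / Nstar
  expect_lt(max(rel), 0.02)
})

test_that("interface relocations are logged and bounded in step size", {
  scn <- scenario("paper-wave-small", duration = 12000, snapshot_dt = 3000)
  th <- simulate_hybrid(scn, realisations = 1, seed = 23)
  rl <- attr(th, "relocations")
  expect_gt(nrow(rl), 0)
  expect_true(all(abs(rl$to - rl$from) == 1 | rl$from == 0 | rl$to == 0))
})
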