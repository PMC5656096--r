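test_that("compartment propensities follow Table-1 rates", {
  p <- wave_params(tau_p = 480)
  pr <- compartment_propensities(ages = c(600, 10), counts = c(2, 3),
                                 a_g1s = 500, p = p)
  expect_equal(pr$birth, 2 / 480)
  expect_equal(pr$death, p$nu * 5)
  expect_equal(pr$diffusion, 60 * p$D_n / p$h^2 * 5 * 2)
  pr0 <- compartment_propensities(0, 1, Inf, p, z = 1)
  expect_equal(pr0$birth, 0)        # quiescent: no mature cells ever
})

test_that("piecewise-hazard waiting times match exponential and thinning oracles", {
  # constant hazard: plain exponential
  set.seed(5)
  draws <- agewave:::.piecewise_event_time_cpp(2e4, c(0, 1e6), 0.37)
  ks <- suppressWarnings(stats::ks.test(draws, "pexp", rate = 0.37))
  expect_gt(ks$p.value, 0.01)
  # hazard stepping up at t* = 3 (a cohort crossing): vs thinning oracle
  breaks <- c(0, 3, 40); levels <- c(0.15, 0.6)
  set.seed(6)
  eng <- agewave:::.piecewise_event_time_cpp(2e4, breaks, levels)
  orc <- replicate(2e4, thinning_time(breaks, levels))
  expect_lt(mean(!is.finite(eng)), 1e-3)
  ks2 <- suppressWarnings(stats::ks.test(eng, orc))
  expect_gt(ks2$p.value, 0.01)
  # no-event beyond a short horizon
  set.seed(7)
  short <- agewave:::.piecewise_event_time_cpp(2e3, c(0, 0.1), 0.5)
  p_none <- mean(!is.finite(short))
  expect_lt(abs(p_none - exp(-0.05)), 3 * sqrt(exp(-0.05) * (1 - exp(-0.05)) / 2e3))
})

test_that("trajectories are reproducible from the seed", {
  scn <- scenario("paper-wave-small", duration = 3000, snapshot_dt = 1000)
  t1 <- simulate_full(scn, realisations = 2, seed = 99)
  t2 <- simulate_full(scn, realisations = 2, seed = 99)
  expect_identical(t1$N, t2$N)
  expect_identical(t1$c, t2$c)
  # single realisation k is reproducible in isolation
  t2b <- simulate_full(scn, realisations = 1,
                       seed = 99 + 0)   # realisation 1 of the pair
  expect_identical(t2b$N, t1$N[t1$realisation == 1])
})

test_that("diffusion-only dynamics conserves cells and their ages", {
  p <- fast_params(nu = 1e-12, D_n = 4e-6, N_L = 6)
  p$cellcycle <- quiescent_cellcycle()   # no birth, ever
  N0 <- c(0, 0, 120, 0, 0, 0)
  scn <- make_scn(p, N0, duration = 4000, snapshot_dt = 500, c_init = 1)
  tr <- simulate_full(scn, seed = 3, return_state = TRUE)
  tot <- total_by_time(tr)
  expect_true(all(tot$N == 120))
  # ages advance as t + a0: the multiset of birth times is preserved
  st <- attr(tr, "states")[[1]]
  bt <- sort(unlist(lapply(st$compartments, function(cp)
    rep(cp$birth_time, cp$count))))
  expect_equal(length(bt), 120)
  expect_true(all(bt <= 0))              # all cells predate t = 0
  # and the population spreads off the seeded compartment
  final <- tr[tr$time == 4000, ]
  expect_gt(sum(final$N > 0), 1)
})

test_that("pure death matches the analytic death chain", {
  p <- fast_params(nu = 2e-3, D_n = 1e-30, N_L = 3)
  p$cellcycle <- quiescent_cellcycle()
  n0 <- 10
  N0 <- c(0, n0, 0)
  Tq <- 900
  scn <- make_scn(p, N0, duration = Tq, snapshot_dt = Tq, c_init = 1)
  nrun <- 400
  extinct <- vapply(seq_len(nrun), function(k) {
    tr <- simulate_full(scn, seed = 1000 + k)
    sum(tr$N[tr$time == Tq]) == 0
  }, logical(1))
  p_true <- (1 - exp(-p$nu * Tq))^n0     # iid exponential deaths
  se <- sqrt(p_true * (1 - p_true) / nrun)
  expect_lt(abs(mean(extinct) - p_true), 3.5 * se)
})

test_that("single-compartment growth follows the Euler-Lotka rate", {
  p <- fast_params(nu = 2e-3, D_n = 1e-30, N_L = 3, c_scale = 1)
  # frozen oxygen at 1 uM; calibrate so A(1) = 150 min
  p$cellcycle$a_plus <- 150 * exp(1)
  sol <- growth_rate(150, p$nu, p$tau_p)
  expect_gt(sol$lambda, 5e-4)
  Tq <- 1500
  scn <- make_scn(p, c(0, 60, 0), duration = Tq, snapshot_dt = Tq / 2,
                  c_init = 1)
  nrun <- 150
  finals <- vapply(seq_len(nrun), function(k) {
    tr <- simulate_full(scn, seed = 5000 + k, oxygen = "frozen")
    sum(tr$N[tr$time == Tq])
  }, 0)
  expected <- 60 * exp(sol$lambda * Tq)
  se <- sd(finals) / sqrt(nrun)
  expect_lt(abs(mean(finals) - expected), 4 * se)
})

test_that("bulk age structure converges to the equilibrium distribution", {
  p <- fast_params(nu = 2e-3, D_n = 1e-30, N_L = 3)
  p$cellcycle$a_plus <- 150 * exp(1)
  sol <- growth_rate(150, p$nu, p$tau_p)
  dist <- equilibrium_age_distribution(sol)
  Tq <- 2500
  scn <- make_scn(p, c(0, 30, 0), duration = Tq, snapshot_dt = Tq,
                  c_init = 1)
  ages <- unlist(lapply(1:25, function(k) {
    tr <- simulate_full(scn, seed = 7000 + k, oxygen = "frozen",
                        return_state = TRUE)
    st <- attr(tr, "states")[[1]]
    cp <- st$compartments[[2]]
    rep(st$time - cp$birth_time, cp$count)
  }))
  expect_gt(length(ages), 3000)
  brk <- c(seq(0, 1200, by = 40), Inf)
  emp <- as.vector(table(cut(ages, brk))) / length(ages)
  theo <- diff(peq_age(c(seq(0, 1200, by = 40), 1e9), dist))
  expect_lt(sum(abs(emp - theo)), 0.05)
})

test_that("results are insensitive to halving the oxygen sync interval", {
  scn1 <- scenario("paper-wave-small", duration = 12000, snapshot_dt = 3000)
  scn2 <- scenario("paper-wave-small", duration = 12000, snapshot_dt = 3000,
                   sync_dt = 25)
  m1 <- total_by_time(simulate_full(scn1, realisations = 4, seed = 21,
                                    sync_dt = 50))
  m2 <- total_by_time(simulate_full(scn2, realisations = 4, seed = 77,
                                    sync_dt = 25))
  a1 <- tapply(m1$N, m1$time, mean); a2 <- tapply(m2$N, m2$time, mean)
  # ensemble means agree within stochastic error
  sdev <- tapply(m1$N, m1$time, sd)
  expect_true(all(abs(a1 - a2)[-1] < 4 * (sdev[-1] / sqrt(4)) + 0.02 * a1[-1]))
})
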