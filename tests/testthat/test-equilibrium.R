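test_that("growth rate has the closed-form degenerate limits", {
  nu <- 0.0000416667; tau_p <- 480
  expect_equal(growth_rate(0, nu, tau_p)$lambda, 1 / 480 - nu)
  expect_equal(growth_rate(Inf, nu, tau_p)$lambda, -nu)
  sol <- growth_rate(5000, nu, tau_p)
  expect_lt(abs(sol$residual), 1e-10)
  expect_gt(sol$lambda, -nu)
})

test_that("growth rate decreases monotonically with the threshold age", {
  lam <- vapply(c(0, 10, 100, 1000, 5000, 2e4, 1e5),
                function(A) growth_rate(A, 2e-3, 100)$lambda, 0)
  expect_true(all(diff(lam) < 0))
})

test_that("growth rate matches the age-discretised dynamics oracle", {
  nu <- 2e-3; b <- 1 / 100
  for (A in c(50, 150, 400)) {
    sol <- growth_rate(A, nu, 100)
    expect_equal(bf_growth_rate(nu, b, A), sol$lambda, tolerance = 1e-3)
  }
})

test_that("oracle's late-time age profile is the equilibrium distribution", {
  nu <- 2e-3; b <- 1 / 100; A <- 150
  sol <- growth_rate(A, nu, 100)
  dist <- equilibrium_age_distribution(sol)
  bf <- bf_age_dynamics(nu, b, A, dt = 0.25, amax = 2500, T = 2500)
  l1 <- sum(abs(bf$profile - deq_age(bf$ages, dist))) * 0.25
  expect_lt(l1, 1e-2)
})

test_that("mode growth rates subtract the diffusion eigenvalue", {
  sol <- growth_rate(100, 2e-3, 100)
  expect_equal(mode_growth_rate(sol, 0, 10), sol$lambda)
  expect_equal(mode_growth_rate(sol, 1, pi), sol$lambda - 1)
  lam_k <- vapply(0:5, mode_growth_rate, 0, sol = sol, L = 20)
  expect_true(all(diff(lam_k) < 0))
})

test_that("rescaled-time conversion pins nu*a = (eps1/eps2)*gamma", {
  p <- wave_params()
  g <- dimensionless_groups(p)
  a_min <- 3210
  gamma <- a_min / (p$h^2 / p$D_n / 60)       # a / tau_n(min)
  expect_equal(p$nu * a_min, (g$eps1 / g$eps2) * gamma, tolerance = 1e-12)
  expect_equal(lambda_dimensionless(1 / (p$h^2 / p$D_n / 60), p), 1)
})

test_that("equilibrium age distribution is normalised, continuous, quadrature-consistent", {
  sol <- growth_rate(150, 2e-3, 100)
  dist <- equilibrium_age_distribution(sol)
  expect_equal(integrate(deq_age, 0, Inf, dist = dist,
                         rel.tol = 1e-12)$value, 1, tolerance = 1e-10)
  eps <- 1e-9
  expect_equal(deq_age(dist$A - eps, dist), deq_age(dist$A + eps, dist),
               tolerance = 1e-6)
  # mass above the threshold: closed form vs quadrature
  quad <- integrate(deq_age, dist$A, Inf, dist = dist, rel.tol = 1e-12)$value
  closed <- mass_fraction_above(dist)
  expect_equal(closed, quad, tolerance = 1e-10)
  # and against the spec-style expression in r1, r2
  r1 <- dist$r1; r2 <- dist$r2; A <- dist$A
  alt <- exp(-r1 * A) * (r1 / r2) /
    (1 - exp(-r1 * A) + exp(-r1 * A) * r1 / r2)
  expect_equal(closed, alt, tolerance = 1e-12)
})

test_that("A = 0 collapses the age distribution to a single exponential", {
  sol <- growth_rate(0, 2e-3, 100)
  dist <- equilibrium_age_distribution(sol)
  x <- seq(0, 500, by = 1)
  expect_equal(deq_age(x, dist), dexp(x, rate = dist$r2), tolerance = 1e-12)
})

test_that("equilibrium birth rate: both routes agree and B - nu = lambda", {
  nu <- 2e-3; tau_p <- 100
  for (A in seq(0, 2000, length.out = 50)) {
    sol <- growth_rate(A, nu, tau_p)
    B1 <- equilibrium_birth_rate(sol)
    B2 <- equilibrium_birth_rate(sol, method = "closed_form")
    expect_equal(B1, B2, tolerance = 1e-10)
    expect_lt(abs(B1 - nu - sol$lambda), 1e-8)
  }
  expect_equal(equilibrium_birth_rate(growth_rate(Inf, nu, tau_p)), 0)
})

test_that("equilibrium-age sampling matches the distribution", {
  set.seed(42)
  # A = 0 case against the exponential reference
  sol0 <- growth_rate(0, 2e-3, 100)
  d0 <- equilibrium_age_distribution(sol0)
  x0 <- req_age(1e5, d0)
  ks <- suppressWarnings(stats::ks.test(x0, "pexp", rate = d0$r2))
  expect_gt(ks$p.value, 0.01)
  # general case: empirical mature fraction within 3 SE of the closed form
  sol <- growth_rate(150, 2e-3, 100)
  dist <- equilibrium_age_distribution(sol)
  x <- req_age(1e5, dist)
  fr <- mass_fraction_above(dist)
  se <- sqrt(fr * (1 - fr) / 1e5)
  expect_lt(abs(mean(x >= dist$A) - fr), 3 * se)
  # quantile edge case
  expect_equal(qeq_age(0, dist), 0)
})

test_that("non-normalisable distributions are rejected", {
  sol <- growth_rate(Inf, 2e-3, 100)   # lambda = -nu: r1 = 0
  expect_error(equilibrium_age_distribution(sol), "normalisable")
})

test_that("equilibrium table exposes the oxygen dependence", {
  p <- scenario("paper-wave-small")$params
  tab <- equilibrium_table(c(0.1, 0.2, 1, 4), p)
  expect_equal(nrow(tab), 4)
  expect_true(all(diff(tab$lambda) > 0))     # more oxygen, faster growth
  expect_equal(tab$B - p$nu, tab$lambda, tolerance = 1e-8)
})
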