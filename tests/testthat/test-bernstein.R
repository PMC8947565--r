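test_that("bernstein basis matches closed forms and sums to one", {
  expect_equal(bernstein_basis(0, 0, 0.3), 1)
  expect_equal(bernstein_basis(7, 0, 0), 1)        # (1-0)^m at x = 0
  expect_equal(bernstein_basis(2, 1, 0.5), 0.5)    # 2 * 0.5 * 0.5
  for (x in c(0, 0.17, 0.5, 0.99, 1))
    expect_equal(sum(bernstein_basis(5, 0:5, x)), 1, tolerance = 1e-12)
  # stays finite at large degree (log-scale binomial coefficients)
  expect_true(all(is.finite(bernstein_basis(300, 0:300, 0.37))))
  expect_error(bernstein_basis(3, 4, 0.5), "0..m")
  expect_error(bernstein_basis(3, -1, 0.5), "0..m")
})

test_that("empirical cdf counts with <= and spans [0, 1]", {
  s <- unit_sample(c(0.2, 0.5, 0.8))
  expect_equal(empirical_cdf(s, 0), 0)
  expect_equal(empirical_cdf(s, 1), 1)
  expect_equal(empirical_cdf(s, 0.5), 2 / 3)   # right-continuity: 0.5 counted
  expect_equal(empirical_cdf(s, 0.49), 1 / 3)
  # non-decreasing in t
  ts <- seq(-0.5, 1.5, by = 0.01)
  expect_true(all(diff(empirical_cdf(s, ts)) >= 0))
  expect_error(unit_sample(numeric(0)))
})

test_that("vitale weights are empirical-cdf increments", {
  fit <- fit_vitale(c(0.2, 0.5, 0.8), m = 2)
  expect_equal(fit$weights, c(2 / 3, 1 / 3))
  expect_equal(fit_vitale(c(0.1, 0.9), m = 2)$weights, c(0.5, 0.5))
  # m = 1: single basis function, flat density
  f1 <- fit_vitale(c(0.3, 0.6), m = 1)
  expect_equal(f1$weights, 1)
  expect_equal(evaluate_vitale(f1, c(0, 0.4, 1)), rep(1, 3))
  expect_error(fit_vitale(c(0.2, 0.5), m = 0), "positive")
  # observations at 0 remove mass, with a warning
  expect_warning(s0 <- unit_sample(c(0, 0.5)), "exactly at 0")
  expect_equal(sum(fit_vitale(s0, 4)$weights), 0.5)
})

test_that("vitale evaluation matches the beta-mixture oracle", {
  fit <- fit_vitale(c(0.2, 0.5, 0.8), m = 2)
  expect_equal(evaluate_vitale(fit, 0), 4 / 3)
  expect_equal(evaluate_vitale(fit, 1), 2 / 3)
  set.seed(42)
  for (m in c(1, 3, 7, 20)) {
    x <- rbeta(40, 2, 5)
    fit <- fit_vitale(x, m)
    grid <- seq(0, 1, length.out = 101)
    expect_equal(evaluate_vitale(fit, grid),
                 vitale_oracle(fit$weights, m, grid), tolerance = 1e-12)
    # density: nonnegative, unit mass
    expect_true(all(evaluate_vitale(fit, grid) >= 0))
    expect_equal(quad_mass(function(z) evaluate_vitale(fit, z)), 1,
                 tolerance = 1e-6)
  }
  expect_error(evaluate_vitale(fit, 1.2), "\\[0, 1\\]")
})

test_that("bernstein-mixture EM has the expected fixed points", {
  # symmetric data, symmetric start: p never moves
  sym <- fit_guan(c(0.25, 0.75), m = 1, p0 = c(0.5, 0.5))
  expect_equal(sym$p, c(0.5, 0.5), tolerance = 1e-12)
  # single hand-computed step: B10(0.25) = 1.5, B11(0.25) = 0.5
  one <- fit_guan(0.25, m = 1, p0 = c(0.5, 0.5), max_iter = 1L)
  expect_equal(one$p, c(0.75, 0.25), tolerance = 1e-12)
  # m = 0: single component, flat density
  flat <- fit_guan(c(0.2, 0.9), m = 0)
  expect_equal(flat$p, 1)
  expect_equal(evaluate_guan(flat, c(0.1, 0.8)), c(1, 1))
  expect_error(fit_guan(c(0.2, 0.8), m = 1, p0 = c(0.9, 0.3)), "probability")
})

test_that("bernstein-mixture estimates are densities on the simplex", {
  set.seed(7)
  x <- rbeta(60, 3, 2)
  for (m in c(2, 5, 12)) {
    fit <- fit_guan(x, m)
    expect_true(all(fit$p >= 0))
    expect_equal(sum(fit$p), 1, tolerance = 1e-9)
    grid <- seq(0, 1, length.out = 201)
    expect_true(all(evaluate_guan(fit, grid) >= 0))
    expect_equal(quad_mass(function(z) evaluate_guan(fit, z)), 1,
                 tolerance = 1e-6)
    # EM monotonicity of the observed log-likelihood
    expect_true(all(diff(fit$loglik) >= -1e-8))
  }
})
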