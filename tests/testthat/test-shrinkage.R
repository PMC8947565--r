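flat <- function(x) rep(1, length(x))

test_that("weight posteriors follow Bayes's formula", {
  # identical components: posterior equals the prior weight
  expect_equal(lambda_e_step(0.3, c(1, 2, 5), c(1, 2, 5)), rep(0.3, 3))
  expect_equal(lambda_e_step(0.5, 2, 1), 2 / 3)
  # boundary weight: posterior saturates wherever f1 > 0
  expect_equal(lambda_e_step(1, c(2, 0.1), c(1, 5)), c(1, 1))
  expect_equal(lambda_e_step(0, c(2, 0.1), c(1, 5)), c(0, 0))
  expect_error(lambda_e_step(1.2, 1, 1), "\\[0, 1\\]")
  expect_error(lambda_e_step(0.5, c(1, 2), 1), "equal length")
})

test_that("weight EM iterates as the hand calculation prescribes", {
  # identical components: every iterate is a fixed point
  fix <- fit_lambda_em(c(0.2, 0.8), flat, flat, lam0 = 0.5)
  expect_equal(fix$lambda, 0.5, tolerance = 1e-12)
  # single observation, f1 = 2, f2 = 1: iterates 1/2, 2/3, 4/5, 8/9, ...
  tr <- fit_lambda_em(0.5, function(x) rep(2, length(x)), flat,
                      lam0 = 0.5, max_iter = 4L)$trace
  expect_equal(tr, c(1 / 2, 2 / 3, 4 / 5, 8 / 9, 16 / 17), tolerance = 1e-12)
  # vanishing parametric component: one iteration drives lambda to 1
  z <- fit_lambda_em(c(0.3, 0.6), flat, function(x) rep(0, length(x)),
                     lam0 = 0.5)
  expect_equal(z$lambda, 1)
  expect_error(fit_lambda_em(0.5, flat, flat, lam0 = -0.1), "\\[0, 1\\]")
})

test_that("weight iterates stay in [0,1] and the likelihood ascends", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    shp <- runif(4, 0.5, 5)
    em <- fit_lambda_em(runif(n),
                        function(x) dbeta(x, shp[1], shp[2]),
                        function(x) dbeta(x, shp[3], shp[4]),
                        lam0 = runif(1))
    expect_true(all(em$trace >= 0 & em$trace <= 1))
    expect_true(all(diff(em$loglik) >= -1e-8))
  }
})

test_that("the fitted estimator is the convex combination of its parts", {
  set.seed(31)
  x <- rbeta(120, 2, 4)
  fit <- fit_shrinkage(x, m = 8, K = 1, seed = 2)
  expect_gte(fit$lambda, 0)
  expect_lte(fit$lambda, 1)
  grid <- seq(0, 1, length.out = 51)
  expect_equal(evaluate_shrinkage(fit, grid),
               fit$lambda * evaluate_vitale(fit$vitale, grid) +
                 (1 - fit$lambda) * gmm_density(fit$gmm$params, grid))
  # deterministic replay
  fit2 <- fit_shrinkage(x, m = 8, K = 1, seed = 2)
  expect_identical(fit$lambda, fit2$lambda)
  # lambda at the boundaries reduces to the components exactly
  fit$lambda <- 1
  expect_equal(evaluate_shrinkage(fit, grid),
               evaluate_vitale(fit$vitale, grid))
  fit$lambda <- 0
  expect_equal(evaluate_shrinkage(fit, grid),
               gmm_density(fit$gmm$params, grid))
  expect_error(evaluate_shrinkage(fit, 1.5), "\\[0, 1\\]")
})

test_that("uniform data give a near-flat estimate", {
  set.seed(41)
  fit <- fit_shrinkage(runif(400), m = 3, K = 1, seed = 1)
  grid <- seq(0.05, 0.95, length.out = 19)
  expect_true(all(abs(evaluate_shrinkage(fit, grid) - 1) < 0.35))
})

test_that("estimator mass is lambda + (1 - lambda) * parametric mass", {
  set.seed(51)
  x <- pmin(pmax(rnorm(150, 0.5, 0.1), 0.01), 0.99)
  fit <- fit_shrinkage(x, m = 12, K = 1, seed = 3)
  total <- quad_mass(function(z) evaluate_shrinkage(fit, z))
  p <- fit$gmm$params
  gmass <- sum(p$pi * (pnorm(1, p$mu, p$sigma) - pnorm(0, p$mu, p$sigma)))
  expect_equal(total, fit$lambda + (1 - fit$lambda) * gmass,
               tolerance = 1e-4)
  expect_equal(fit$f2_mass_unit, gmass, tolerance = 1e-4)
})

test_that("confidence intervals follow the plug-in normal formula", {
  # force a known state: fhat = 1, lambda = 1, n = 100, m = 16
  est <- structure(list(lambda = 1, m = 16L, n = 100L,
                        vitale = fit_vitale(c(0.4, 0.6), m = 1),
                        f2 = function(x) rep(1, length(x)),
                        gmm = NULL, f2_mass_unit = 1),
                   class = "shrinkage_fit")
  ci <- asymptotic_ci(est, 0.5, alpha = 0.05, convention = "printed")
  expect_equal(ci$fit, 1)
  expect_equal(ci$upper - ci$fit, 0.07361, tolerance = 1e-4)
  ci2 <- asymptotic_ci(est, 0.5, alpha = 0.05, convention = "prop2")
  expect_equal(ci2$upper - ci2$fit, 0.29444, tolerance = 1e-4)
  # lambda = 0: the interval collapses to the point estimate
  est$lambda <- 0
  ci0 <- asymptotic_ci(est, c(0.2, 0.5, 0.8))
  expect_equal(ci0$lower, ci0$fit)
  expect_equal(ci0$upper, ci0$fit)
  expect_error(asymptotic_ci(est, 0), "strictly inside")
  expect_error(asymptotic_ci(est, 0.5, alpha = 1.2), "\\(0, 1\\)")
})

test_that("with the weight held fixed, the estimate converges to its limit", {
  # plug-in combination lambda*f + (1-lambda)*f2 at x = 0.5 for growing n,
  # m = floor(sqrt(n / log n)); truth Beta(2,2), single-Gaussian parametric
  # component with pseudo-true parameters (moments of Beta(2,2))
  lam <- 0.6
  truth <- function(x) dbeta(x, 2, 2)
  target <- lam * truth(0.5) +
    (1 - lam) * dnorm(0.5, 0.5, sqrt(0.05))
  err <- sapply(c(300, 20000), function(n) {
    set.seed(n)
    x <- rbeta(n, 2, 2)
    m <- floor(sqrt(n / log(n)))
    v <- fit_vitale(x, m)
    g <- fit_gmm_em(x, K = 1, seed = 1)
    est <- lam * evaluate_vitale(v, 0.5) +
      (1 - lam) * gmm_density(g$params, 0.5)
    abs(est - target)
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})
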