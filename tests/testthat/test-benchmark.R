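cat6 <- density_catalog()

test_that("catalogue densities are correct and integrate to one", {
  expect_equal(cat6$a$pdf(0.5), 0.5 * dbeta(0.5, 3, 9) + 0.5 * dbeta(0.5, 9, 3))
  expect_equal(cat6$d$pdf(0), 0.5)  # chi2(2) = Exp(rate 1/2) at the origin
  expect_equal(cat6$e$pdf(0), 0.5 * 6)  # shape-rate: G(1,6) is Exp(6)
  masses <- c(
    quad_mass(cat6$a$pdf), quad_mass(cat6$b$pdf),
    quad_mass(cat6$c$pdf, -12, 10), quad_mass(cat6$d$pdf, 0, 60),
    quad_mass(cat6$e$pdf, 0, 40), quad_mass(cat6$f$pdf, 0, 40))
  expect_equal(masses, rep(1, 6), tolerance = 1e-4)
})

test_that("samplers are seeded and hit the mixture moments", {
  s1 <- sample_density(cat6$a, 50, seed = 7)
  s2 <- sample_density(cat6$a, 50, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  big <- sample_density(cat6$c, 1e5, seed = 1)
  mix_mean <- 0.25 * 2 + 0.75 * (-3)
  mix_var <- 0.25 * (1 + 2^2) + 0.75 * (1 + 3^2) - mix_mean^2
  expect_lt(abs(mean(big) - mix_mean), 3 * sqrt(mix_var / 1e5))
})

small_cfg <- benchmark_config(m_grid = 1:30, h_grid = seq(0.02, 0.3, 0.02),
                              guan_m_grid = c(2, 5, 10), gap_B = 10,
                              K_max = 4, select_grid = 101)

test_that("a trial is deterministic and yields finite errors for all four estimators", {
  r1 <- run_trial(cat6$a, 60, seed = 3, config = small_cfg)
  r2 <- run_trial(cat6$a, 60, seed = 3, config = small_cfg)
  expect_identical(r1, r2)
  expect_setequal(r1$estimator, c("shrinkage", "vitale", "kernel", "guan"))
  expect_true(all(is.finite(r1$ise) & r1$ise >= 0))
  expect_true(all(is.finite(r1$iae) & r1$iae >= 0))
  expect_true(all(is.finite(r1$kl)))
  expect_true(all(r1$param[r1$estimator %in% c("shrinkage", "vitale")]
                  %in% small_cfg$m_grid))
  expect_true(r1$param[r1$estimator == "kernel"] %in% small_cfg$h_grid)
  lam <- r1$lambda[r1$estimator == "shrinkage"]
  expect_gte(lam, 0); expect_lte(lam, 1)
})

test_that("trials work on transformed supports too", {
  r <- run_trial(cat6$f, 60, seed = 5,
                 config = benchmark_config(m_grid = 1:25,
                                           estimators = c("shrinkage", "vitale"),
                                           gap_B = 10, select_grid = 101))
  expect_true(all(is.finite(r$ise)))
  expect_gte(min(r$ise), 0)
})

test_that("benchmark averages equal their single-trial values when N = 1", {
  cfg <- benchmark_config(m_grid = 1:15, estimators = c("shrinkage", "vitale"),
                          gap_B = 10, select_grid = 101)
  bench <- run_benchmark("a", n_list = 60, N = 1, base_seed = 12, config = cfg)
  trial <- run_trial(cat6$a, 60, seed = 13, config = cfg)
  for (est in c("shrinkage", "vitale")) {
    expect_equal(bench$summary$ise[bench$summary$estimator == est],
                 trial$ise[trial$estimator == est])
    expect_equal(bench$summary$kl[bench$summary$estimator == est],
                 trial$kl[trial$estimator == est])
  }
  tidy <- benchmark_tidy(bench)
  expect_setequal(tidy$metric, c("ise", "iae", "kl"))
  expect_equal(nrow(tidy), 6)  # 2 estimators x 3 metrics
  # averages are re-derivable from the stored trial log
  expect_equal(mean(bench$trials$ise[bench$trials$estimator == "vitale"]),
               bench$summary$ise[bench$summary$estimator == "vitale"])
})

test_that("unknown density labels are rejected", {
  expect_error(run_benchmark("z", n_list = 60, N = 1), "unknown density")
})
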