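# Monte-Carlo benchmark harness.  Six test densities on three kinds of
# support, seeded samplers, a per-trial protocol (transform to the unit
# interval, 2/3-1/3 train/test split, tuning-parameter selection by
# minimising the quadrature ISE of the fitted estimator against the
# true transformed density), and averaging of ISE/IAE/KL over trials.

#' The six benchmark densities
#'
#' Returns the catalogue of test densities used by the simulation
#' benchmark, each with its native-support pdf, a sampler, and the
#' support declaration that fixes the transform to the unit interval:
#' \describe{
#'   \item{a}{beta mixture `0.5 B(3,9) + 0.5 B(9,3)` (unit interval)}
#'   \item{b}{beta mixture `0.5 B(3,1) + 0.5 B(10,10)` (unit interval)}
#'   \item{c}{normal mixture `0.25 N(2,1) + 0.75 N(-3,1)` (real line,
#'     arctan map)}
#'   \item{d}{chi-squared with 2 df (half line, `x/(1+x)` map)}
#'   \item{e}{gamma mixture `0.5 G(1,6) + 0.5 G(6,1)` (half line)}
#'   \item{f}{gamma mixture `0.5 G(1,2) + 0.5 G(4,2)` (half line)}
#' }
#' Gamma components are in the shape-rate convention, so `G(1,6)` is
#' exponential with rate 6 (density 6 at the origin: the steep-boundary
#' case every estimator finds hard).
#'
#' @return Named list of `density_spec` objects with fields `label`,
#'   `pdf`, `sampler` (function of `n`, using the current RNG stream),
#'   `support` and `description`.
#' @examples
#' cat6 <- density_catalog()
#' cat6$a$pdf(0.5)
#' @export
density_catalog <- function() {
  mix_sampler <- function(w, draw1, draw2) {
    function(n) {
      z <- stats::rbinom(n, 1L, w)
      x <- numeric(n)
      n1 <- sum(z == 1L)
      if (n1 > 0) x[z == 1L] <- draw1(n1)
      if (n1 < n) x[z == 0L] <- draw2(n - n1)
      x
    }
  }
  spec <- function(label, pdf, sampler, support, description)
    structure(list(label = label, pdf = pdf, sampler = sampler,
                   support = support, description = description),
              class = "density_spec")
  list(
    a = spec("a",
             function(x) 0.5 * stats::dbeta(x, 3, 9) + 0.5 * stats::dbeta(x, 9, 3),
             mix_sampler(0.5, function(k) stats::rbeta(k, 3, 9),
                         function(k) stats::rbeta(k, 9, 3)),
             support_spec("interval", 0, 1),
             "beta mixture 0.5 B(3,9) + 0.5 B(9,3)"),
    b = spec("b",
             function(x) 0.5 * stats::dbeta(x, 3, 1) + 0.5 * stats::dbeta(x, 10, 10),
             mix_sampler(0.5, function(k) stats::rbeta(k, 3, 1),
                         function(k) stats::rbeta(k, 10, 10)),
             support_spec("interval", 0, 1),
             "beta mixture 0.5 B(3,1) + 0.5 B(10,10)"),
    c = spec("c",
             function(x) 0.25 * stats::dnorm(x, 2, 1) + 0.75 * stats::dnorm(x, -3, 1),
             mix_sampler(0.25, function(k) stats::rnorm(k, 2, 1),
                         function(k) stats::rnorm(k, -3, 1)),
             support_spec("real_line"),
             "normal mixture 0.25 N(2,1) + 0.75 N(-3,1)"),
    d = spec("d",
             function(x) stats::dchisq(x, 2),
             function(n) stats::rexp(n, rate = 0.5),
             support_spec("positive_half_line"),
             "chi-squared, 2 degrees of freedom"),
    e = spec("e",
             function(x) 0.5 * stats::dgamma(x, shape = 1, rate = 6) +
               0.5 * stats::dgamma(x, shape = 6, rate = 1),
             mix_sampler(0.5, function(k) stats::rgamma(k, shape = 1, rate = 6),
                         function(k) stats::rgamma(k, shape = 6, rate = 1)),
             support_spec("positive_half_line"),
             "gamma mixture 0.5 G(1,6) + 0.5 G(6,1) (shape-rate)"),
    f = spec("f",
             function(x) 0.5 * stats::dgamma(x, shape = 1, rate = 2) +
               0.5 * stats::dgamma(x, shape = 4, rate = 2),
             mix_sampler(0.5, function(k) stats::rgamma(k, shape = 1, rate = 2),
                         function(k) stats::rgamma(k, shape = 4, rate = 2)),
             support_spec("positive_half_line"),
             "gamma mixture 0.5 G(1,2) + 0.5 G(4,2) (shape-rate)"))
}

#' @export
print.density_spec <- function(x, ...) {
  cat("Benchmark density (", x$label, "): ", x$description, "\n", sep = "")
  print(x$support)
  invisible(x)
}

#' Draw a seeded sample from a benchmark density
#'
#' @param spec a `density_spec` from [density_catalog()].
#' @param n sample size.
#' @param seed integer seed; the caller's RNG stream is not disturbed.
#' @return Numeric vector of `n` draws on the native support.
#' @export
sample_density <- function(spec, n, seed) {
  stopifnot(inherits(spec, "density_spec"), n >= 1)
  with_seed(seed, spec$sampler(n))
}

#' Benchmark configuration
#'
#' Collects the tuning grids and fitting options of [run_trial()] /
#' [run_benchmark()].
#'
#' @param m_grid Bernstein degrees searched for the Vitale and shrinkage
#'   estimators.
#' @param h_grid kernel bandwidths searched.
#' @param estimators subset of `c("shrinkage", "vitale", "kernel",
#'   "guan")` to fit.
#' @param gmm_scale `"native"` fits the Gaussian mixture on the data's
#'   original scale and carries its density to the unit interval by the
#'   change of variables; `"unit"` fits it directly on the transformed
#'   sample.
#' @param K mixture components, `"auto"` for gap-statistic selection.
#' @param K_max,gap_B gap-statistic controls.
#' @param select_grid quadrature points used while scanning the tuning
#'   grids; `metric_grid` points are used for the reported metrics.
#' @param metric_grid quadrature points for the final ISE/IAE/KL.
#' @param share_m if `TRUE` the Vitale estimator is reported at the
#'   degree selected for the shrinkage estimator (one `m1` for both);
#'   if `FALSE` each selects its own degree.
#' @param guan_m_grid degrees searched for the Bernstein-mixture
#'   estimator (defaults to `m_grid`); `guan_tol`, `guan_max_iter`
#'   control its EM.
#' @param lambda_tol,lambda_max_iter EM controls for the shrinkage
#'   weight.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(m_grid = 1:300,
                             h_grid = seq(0.001, 0.300, by = 0.001),
                             estimators = c("shrinkage", "vitale",
                                            "kernel", "guan"),
                             gmm_scale = c("native", "unit"),
                             K = "auto", K_max = 10L, gap_B = 50L,
                             select_grid = 251L, metric_grid = 1001L,
                             share_m = TRUE,
                             guan_m_grid = NULL, guan_tol = 1e-6,
                             guan_max_iter = 200L,
                             lambda_tol = 1e-8, lambda_max_iter = 1000L) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  gmm_scale <- match.arg(gmm_scale)
  if (is.null(guan_m_grid)) guan_m_grid <- m_grid
  structure(list(m_grid = m_grid, h_grid = h_grid, estimators = estimators,
                 gmm_scale = gmm_scale, K = K, K_max = K_max, gap_B = gap_B,
                 select_grid = select_grid, metric_grid = metric_grid,
                 share_m = share_m, guan_m_grid = guan_m_grid,
                 guan_tol = guan_tol, guan_max_iter = guan_max_iter,
                 lambda_tol = lambda_tol,
                 lambda_max_iter = lambda_max_iter),
            class = "benchmark_config")
}

# Interior-offset selection grid and trapezoid x-coordinates.
sel_points <- function(grid) {
  x <- seq(0, 1, length.out = grid)
  list(x = x, x_eval = pmin(pmax(x, BOUNDARY_OFFSET), 1 - BOUNDARY_OFFSET))
}

#' Run one benchmark trial
#'
#' Draws `n` observations from the given density, maps them to the unit
#' interval, shuffles and splits them 2/3 train / 1/3 test, fits the
#' requested estimators on the training set with tuning parameters
#' selected to minimise the quadrature ISE against the true transformed
#' density, and records the final ISE/IAE/KL (and the test-set
#' log-likelihood) of each selected fit.
#'
#' @param spec a `density_spec`.
#' @param n total sample size (at least 6).
#' @param seed integer seed; a trial is fully reproducible from
#'   `(spec, n, seed, config)`.
#' @param config a [benchmark_config()].
#' @return A data frame with one row per estimator: columns `density`,
#'   `n`, `estimator`, `param` (selected `m` or `h`), `K`, `lambda`,
#'   `ise`, `iae`, `kl`, `test_loglik`, `seed`.
#' @export
run_trial <- function(spec, n, seed, config = benchmark_config()) {
  stopifnot(inherits(spec, "density_spec"), n >= 6)
  drawn <- with_seed(seed, {
    x <- spec$sampler(n)
    list(x = x, perm = sample.int(n))
  })
  x_native <- drawn$x
  y_unit <- suppressWarnings(to_unit(x_native, spec$support))$values
  n_train <- round(2 * n / 3)
  idx_train <- drawn$perm[seq_len(n_train)]
  idx_test <- drawn$perm[-seq_len(n_train)]
  train_u <- y_unit[idx_train]
  test_u <- y_unit[idx_test]
  f_true <- transform_density(spec$pdf, spec$support)

  sel <- sel_points(config$select_grid)
  f_true_sel <- f_true(sel$x_eval)

  rows <- list()
  add_row <- function(estimator, param, K, lambda, fhat) {
    met <- density_metrics(fhat, f_true, config$metric_grid)
    rows[[length(rows) + 1L]] <<- data.frame(
      density = spec$label, n = n, estimator = estimator,
      param = param, K = K, lambda = lambda,
      ise = met$ise, iae = met$iae, kl = met$kl,
      test_loglik = sum(log(pmax(fhat(test_u), DENSITY_FLOOR))),
      seed = seed)
  }

  want <- config$estimators
  need_gmm <- "shrinkage" %in% want
  K_sel <- NA_integer_
  f2_fun <- NULL
  if (need_gmm) {
    gdata <- if (config$gmm_scale == "native") x_native[idx_train] else train_u
    K_sel <- if (identical(config$K, "auto"))
      select_K_gap(gdata, K_max = config$K_max, B = config$gap_B, seed = seed)
    else as.integer(config$K)
    gfit <- fit_gmm_em(gdata, K = K_sel, seed = seed)
    f2_fun <- if (config$gmm_scale == "native")
      transform_density(function(z) gmm_density(gfit$params, z), spec$support)
    else function(y) gmm_density(gfit$params, y)
  }

  if ("shrinkage" %in% want || "vitale" %in% want) {
    pick <- select_bernstein_degree(train_u, config$m_grid, f2_fun,
                                    sel, f_true_sel, config)
    if ("shrinkage" %in% want) {
      vit <- fit_vitale(train_u, pick$m_shrink)
      em <- lambda_em(pmax(evaluate_vitale(vit, train_u), 0),
                      pmax(f2_fun(train_u), 0), 0.5,
                      config$lambda_tol, config$lambda_max_iter,
                      track = FALSE)
      lam <- em$lambda
      add_row("shrinkage", pick$m_shrink, K_sel, lam,
              function(x) lam * evaluate_vitale(vit, x) +
                (1 - lam) * f2_fun(x))
    }
    if ("vitale" %in% want) {
      m_v <- if (config$share_m && "shrinkage" %in% want)
        pick$m_shrink else pick$m_vitale
      vit <- fit_vitale(train_u, m_v)
      add_row("vitale", m_v, NA_integer_, NA_real_,
              function(x) evaluate_vitale(vit, x))
    }
  }

  if ("kernel" %in% want) {
    h_best <- select_bandwidth(train_u, config$h_grid, sel, f_true_sel)
    kfit <- fit_kernel(train_u, h_best)
    add_row("kernel", h_best, NA_integer_, NA_real_,
            function(x) evaluate_kernel(kfit, x))
  }

  if ("guan" %in% want) {
    best <- NULL
    for (m in config$guan_m_grid) {
      gf <- fit_guan(train_u, m, tol = config$guan_tol,
                     max_iter = config$guan_max_iter)
      e <- pracma::trapz(sel$x, (evaluate_guan(gf, sel$x_eval) - f_true_sel)^2)
      if (is.null(best) || e < best$e) best <- list(fit = gf, e = e, m = m)
    }
    add_row("guan", best$m, NA_integer_, NA_real_,
            function(x) evaluate_guan(best$fit, x))
  }

  do.call(rbind, rows)
}

# Scan the degree grid once, tracking the ISE-optimal degree for the
# shrinkage combination and for the plain Vitale estimate.  The scan
# runs the weight EM at a relaxed tolerance; run_trial refits the
# weight at the selected degree with the configured tolerance.
select_bernstein_degree <- function(train_u, m_grid, f2_fun, sel,
                                    f_true_sel, config) {
  n_tr <- length(train_u)
  sorted <- sort(train_u)
  pts <- c(train_u, sel$x_eval)
  np <- length(pts)
  have_f2 <- !is.null(f2_fun)
  if (have_f2) {
    f2_train <- pmax(f2_fun(train_u), 0)
    f2_sel <- f2_fun(sel$x_eval)
  }
  scan_tol <- max(config$lambda_tol, 1e-6)
  best_s <- list(e = Inf, m = NA_integer_)
  best_v <- list(e = Inf, m = NA_integer_)
  in_grid <- rep(FALSE, max(m_grid))
  in_grid[m_grid] <- TRUE
  # Bb holds the binomial basis b_k(m-1, pts), k = 0..m-1, advanced by
  # the degree-elevation recurrence
  #   b_k(d+1, x) = x b_{k-1}(d, x) + (1-x) b_k(d, x),
  # which is numerically stable (nonnegative terms summing to 1) and
  # avoids a fresh O(m) set of beta-density evaluations per degree.
  Bb <- matrix(1, np, 1L)
  omp <- 1 - pts
  for (m in seq_len(max(m_grid))) {
    if (m > 1L)
      Bb <- cbind(omp * Bb, 0) + cbind(0, pts * Bb)
    if (!in_grid[m]) next
    w <- diff(findInterval((0:m) / m, sorted)) / n_tr
    f1_all <- m * drop(Bb %*% w)
    f1_train <- f1_all[seq_len(n_tr)]
    f1_sel <- f1_all[-seq_len(n_tr)]
    e_v <- pracma::trapz(sel$x, (f1_sel - f_true_sel)^2)
    if (e_v < best_v$e) best_v <- list(e = e_v, m = m)
    if (have_f2) {
      em <- lambda_em(pmax(f1_train, 0), f2_train, 0.5,
                      scan_tol, config$lambda_max_iter, track = FALSE)
      fh <- em$lambda * f1_sel + (1 - em$lambda) * f2_sel
      e_s <- pracma::trapz(sel$x, (fh - f_true_sel)^2)
      if (e_s < best_s$e) best_s <- list(e = e_s, m = m)
    }
  }
  list(m_shrink = best_s$m, m_vitale = best_v$m)
}

select_bandwidth <- function(train_u, h_grid, sel, f_true_sel) {
  d <- outer(sel$x_eval, train_u, "-")
  errs <- vapply(h_grid, function(h) {
    fh <- rowMeans(stats::dnorm(d / h)) / h
    pracma::trapz(sel$x, (fh - f_true_sel)^2)
  }, numeric(1))
  h_grid[which.min(errs)]
}

#' Run the full Monte-Carlo benchmark
#'
#' Repeats [run_trial()] `N` times per (density, sample size) scenario
#' with seeds `base_seed + 1, ..., base_seed + N`, and averages the
#' ISE/IAE/KL of each estimator over trials.
#'
#' @param densities character vector of catalogue labels (subset of
#'   `"a".."f"`), or a list of `density_spec`s.
#' @param n_list integer vector of sample sizes.
#' @param N number of Monte-Carlo trials per scenario.
#' @param base_seed integer; trial `k` of every scenario uses seed
#'   `base_seed + k`, so any single trial can be replayed.
#' @param config a [benchmark_config()].
#' @return An object of class `benchmark_result`: list with `summary`
#'   (mean and Monte-Carlo standard error of each metric per density,
#'   `n` and estimator) and `trials` (the per-trial log).
#' @export
run_benchmark <- function(densities = c("a", "b", "c", "d", "e", "f"),
                          n_list = c(50L, 100L, 200L), N = 500L,
                          base_seed = 0L, config = benchmark_config()) {
  stopifnot(N >= 1)
  if (is.character(densities)) {
    cat6 <- density_catalog()
    bad <- setdiff(densities, names(cat6))
    if (length(bad))
      stop("unknown density label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    densities <- cat6[densities]
  }
  trials <- list()
  for (spec in densities)
    for (n in n_list)
      for (k in seq_len(N))
        trials[[length(trials) + 1L]] <-
          run_trial(spec, n, seed = base_seed + k, config = config)
  trials <- do.call(rbind, trials)

  agg <- stats::aggregate(cbind(ise, iae, kl) ~ density + n + estimator,
                          data = trials, FUN = mean)
  se <- stats::aggregate(cbind(ise, iae, kl) ~ density + n + estimator,
                         data = trials,
                         FUN = function(v) stats::sd(v) / sqrt(length(v)))
  names(se)[4:6] <- c("ise_se", "iae_se", "kl_se")
  summary <- merge(agg, se, by = c("density", "n", "estimator"))
  summary <- summary[order(summary$density, summary$n, summary$estimator), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, trials = trials, N = N,
                 base_seed = base_seed),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, digits = 6, ...) {
  cat("Monte-Carlo benchmark:", x$N, "trial(s) per scenario, base seed",
      x$base_seed, "\n\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Tidy long-format view of a benchmark result
#'
#' @param result a `benchmark_result`.
#' @return Data frame with columns `density`, `n`, `estimator`,
#'   `metric`, `value`, `se`, `N`, `base_seed`.
#' @export
benchmark_tidy <- function(result) {
  stopifnot(inherits(result, "benchmark_result"))
  s <- result$summary
  out <- do.call(rbind, lapply(c("ise", "iae", "kl"), function(metric)
    data.frame(density = s$density, n = s$n, estimator = s$estimator,
               metric = metric, value = s[[metric]],
               se = s[[paste0(metric, "_se")]],
               N = result$N, base_seed = result$base_seed)))
  out[order(out$density, out$n, out$metric, out$estimator), ,
      drop = FALSE]
}
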