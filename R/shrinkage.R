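# The shrinkage estimator: a convex combination
#   f_hat(x) = lambda * f1(x) + (1 - lambda) * f2(x)
# of the nonparametric Vitale estimate f1 and a parametric Gaussian
# mixture f2, both on the unit interval.  The weight lambda is estimated
# by an EM step that treats the component membership of each observation
# as a hidden Bernoulli label.

#' EM E-step for the shrinkage weight
#'
#' Bayes posterior that an observation was generated by the
#' nonparametric component:
#' \eqn{\bar\tau_{i1} = \lambda f_1(X_i) /
#'   \{\lambda f_1(X_i) + (1-\lambda) f_2(X_i)\}};
#' the parametric posterior is its complement.
#'
#' @param lam current weight in \eqn{[0,1]}.
#' @param f1_vals,f2_vals nonnegative component density values at the
#'   observations (equal length).
#' @return Posterior vector in \eqn{[0,1]}, one entry per observation.
#' @examples
#' lambda_e_step(0.5, 2, 1)  # 2/3
#' @export
lambda_e_step <- function(lam, f1_vals, f2_vals) {
  if (lam < 0 || lam > 1)
    stop("'lam' must lie in [0, 1]", call. = FALSE)
  if (length(f1_vals) != length(f2_vals))
    stop("component density vectors must have equal length", call. = FALSE)
  num <- lam * f1_vals
  den <- pmax(num + (1 - lam) * f2_vals, DENSITY_FLOOR)
  num / den
}

#' Estimate the shrinkage weight by EM
#'
#' Iterates the E-step [lambda_e_step()] and the M-step
#' \eqn{\lambda^{(t+1)} = n^{-1}\sum_i \bar\tau_{i1}^{(t)}} until
#' \eqn{|\lambda^{(t+1)} - \lambda^{(t)}| < } `tol` or `max_iter`.  The
#' two component densities are held fixed; the mixture log-likelihood
#' \eqn{\sum_i \log\{\lambda f_1(X_i) + (1-\lambda) f_2(X_i)\}} is
#' non-decreasing along the iteration.
#'
#' @param sample a [unit_sample] or numeric vector on \eqn{[0,1]}.
#' @param f1,f2 vectorised density functions on \eqn{[0,1]} (the
#'   nonparametric and parametric components).
#' @param lam0 starting weight in \eqn{[0,1]}.
#' @param tol convergence tolerance on \eqn{|\Delta\lambda|}.
#' @param max_iter iteration cap.
#' @return List with `lambda`, `trace` (iterates, starting at `lam0`),
#'   `loglik` (trace), `iterations`, `converged`.
#' @export
fit_lambda_em <- function(sample, f1, f2, lam0 = 0.5, tol = 1e-8,
                          max_iter = 1000L) {
  sample <- as_unit_sample(sample)
  if (length(lam0) != 1L || lam0 < 0 || lam0 > 1)
    stop("'lam0' must lie in [0, 1]", call. = FALSE)
  f1v <- pmax(f1(sample$values), 0)
  f2v <- pmax(f2(sample$values), 0)
  if (any(f1v == 0 & f2v == 0))
    warning("both component densities vanish at an observation; ",
            "posteriors fall back on the density floor", call. = FALSE)
  lambda_em(f1v, f2v, lam0, tol, max_iter)
}

# Core iteration on precomputed component density values.  track = FALSE
# skips the log-likelihood and iterate traces (used in tuning scans).
lambda_em <- function(f1v, f2v, lam0, tol, max_iter, track = TRUE) {
  n <- length(f1v)
  lam <- lam0
  trace <- if (track) numeric(max_iter + 1L) else NULL
  ll <- if (track) numeric(max_iter) else NULL
  if (track) trace[1L] <- lam
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    num <- lam * f1v
    mix <- num + (1 - lam) * f2v + DENSITY_FLOOR
    if (track) ll[iter] <- sum(log(mix))
    lam_new <- sum(num / mix) / n
    if (track) trace[iter + 1L] <- lam_new
    if (abs(lam_new - lam) < tol) { lam <- lam_new; converged <- TRUE; break }
    lam <- lam_new
  }
  list(lambda = lam,
       trace = if (track) trace[seq_len(iter + 1L)],
       loglik = if (track) ll[seq_len(iter)],
       iterations = iter, converged = converged)
}

#' Fit the shrinkage density estimator
#'
#' Three steps: (1) the Vitale Bernstein estimator of degree `m`
#' ([fit_vitale()]); (2) a parametric Gaussian mixture, gap-selected K
#' when `K = "auto"` ([fit_gmm_em()], [select_K_gap()]); (3) the weight
#' \eqn{\lambda} by EM over the two fixed component densities
#' ([fit_lambda_em()]).
#'
#' By default the mixture is fitted to the unit-interval sample itself.
#' Alternatively `f2` supplies any fixed parametric density on
#' \eqn{(0,1)} — typically a Gaussian mixture fitted on the data's
#' native scale and carried to the unit interval with
#' [transform_density()] — in which case step (2) is skipped.
#'
#' @param sample a [unit_sample] or numeric vector on \eqn{[0,1]}.
#' @param m Bernstein degree for the nonparametric component.
#' @param K number of mixture components or `"auto"` (ignored when `f2`
#'   is supplied).
#' @param f2 optional vectorised density function on \eqn{(0,1)} used as
#'   the parametric component.
#' @param lam0,tol,max_iter EM controls for the weight (see
#'   [fit_lambda_em()]).
#' @param seed integer seed for the mixture initialisation / K selection.
#' @return An object of class `shrinkage_fit`: fields `lambda`,
#'   `vitale` (a `vitale_fit`), `gmm` (a `gmm_fit`, or `NULL` when `f2`
#'   was supplied), `f2` (the parametric density function), `m`, `n`,
#'   `lambda_em` (the optimiser trace), and `f2_mass_unit`, the mass the
#'   parametric component places on \eqn{[0,1]} (flagged by `print()`
#'   when below 0.99, since then the combined estimate integrates to
#'   less than 1).
#' @examples
#' x <- rbeta(100, 2, 5)
#' fit <- fit_shrinkage(x, m = 10, K = 1)
#' fit$lambda
#' @export
fit_shrinkage <- function(sample, m, K = "auto", f2 = NULL, lam0 = 0.5,
                          tol = 1e-8, max_iter = 1000L, seed = 1L) {
  sample <- as_unit_sample(sample)
  vit <- fit_vitale(sample, m)
  gmm <- NULL
  if (is.null(f2)) {
    gmm <- fit_gmm_em(sample$values, K = K, seed = seed)
    f2 <- function(x) gmm_density(gmm$params, x)
  } else {
    stopifnot(is.function(f2))
  }
  em <- lambda_em(pmax(evaluate_vitale(vit, sample$values), 0),
                  pmax(f2(sample$values), 0),
                  lam0, tol, max_iter)
  mass <- tryCatch(
    pracma::trapz(seq(1e-9, 1 - 1e-9, length.out = 2001),
                  f2(seq(1e-9, 1 - 1e-9, length.out = 2001))),
    error = function(e) NA_real_)
  structure(list(lambda = em$lambda, vitale = vit, gmm = gmm, f2 = f2,
                 m = vit$m, n = sample$n, lambda_em = em,
                 f2_mass_unit = mass),
            class = "shrinkage_fit")
}

#' Evaluate a shrinkage density estimate
#'
#' \eqn{\hat f_{n,m}(x) = \hat\lambda \tilde f_1(x) +
#' (1-\hat\lambda) \tilde f_2(x)}.  With \eqn{\hat\lambda = 1} this is
#' exactly the Vitale estimate; with \eqn{\hat\lambda = 0}, the
#' parametric mixture.
#'
#' @param est a `shrinkage_fit`.
#' @param x evaluation points in \eqn{[0,1]} (vectorised).
#' @return Nonnegative density values.
#' @export
evaluate_shrinkage <- function(est, x) {
  stopifnot(inherits(est, "shrinkage_fit"))
  if (any(x < 0) || any(x > 1))
    stop("'x' must lie in [0, 1]", call. = FALSE)
  est$lambda * evaluate_vitale(est$vitale, x) +
    (1 - est$lambda) * est$f2(x)
}

#' Asymptotic confidence interval for the density
#'
#' Pointwise interval based on the limiting normal law of the estimator:
#' \deqn{\hat f_{n,m}(x) \pm z_{1-\alpha/2}\,\hat\lambda\,
#'   \sqrt{\gamma(x)/n}\; m^{\mp 1/4},\qquad
#'   \gamma(x) = f(x)\{4\pi x(1-x)\}^{-1/2},}
#' with \eqn{\gamma} estimated by plugging in the point estimate.  The
#' two conventions differ in the power of \eqn{m}: `"printed"` uses
#' \eqn{m^{-1/4}}, `"prop2"` uses \eqn{m^{+1/4}} (the factor that undoes
#' the \eqn{n^{1/2} m^{-1/4}} normalisation of the limit law).  The
#' factor \eqn{\gamma(x)} diverges at the endpoints, so `x` must be
#' interior.
#'
#' @param est a `shrinkage_fit`.
#' @param x evaluation points strictly inside \eqn{(0,1)}.
#' @param alpha risk level in \eqn{(0,1)} (default 0.05 for 95%).
#' @param convention `"printed"` or `"prop2"`.
#' @return A data frame with columns `x`, `fit`, `lower`, `upper`.
#' @export
asymptotic_ci <- function(est, x, alpha = 0.05,
                          convention = c("printed", "prop2")) {
  stopifnot(inherits(est, "shrinkage_fit"))
  convention <- match.arg(convention)
  if (any(x <= 0) || any(x >= 1))
    stop("'x' must lie strictly inside (0, 1): the variance factor ",
         "diverges at the boundary", call. = FALSE)
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  fhat <- evaluate_shrinkage(est, x)
  gam <- fhat / sqrt(4 * pi * x * (1 - x))
  mfac <- if (convention == "printed") est$m^(-1 / 4) else est$m^(1 / 4)
  hw <- stats::qnorm(1 - alpha / 2) * est$lambda * sqrt(gam / est$n) * mfac
  data.frame(x = x, fit = fhat, lower = fhat - hw, upper = fhat + hw)
}

#' @export
print.shrinkage_fit <- function(x, ...) {
  cat(sprintf("Shrinkage density estimate: lambda = %.4f, m = %d, n = %d\n",
              x$lambda, x$m, x$n))
  if (!is.null(x$gmm))
    cat("  parametric component: Gaussian mixture, K =", x$gmm$K, "\n")
  else
    cat("  parametric component: user-supplied density\n")
  if (is.finite(x$f2_mass_unit) && x$f2_mass_unit < 0.99)
    cat(sprintf("  NOTE: parametric component has mass %.4f on [0,1];\n",
                x$f2_mass_unit),
        " the combined estimate integrates to less than 1\n")
  invisible(x)
}
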