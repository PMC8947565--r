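#' Bernstein polynomial basis
#'
#' Evaluates the Bernstein basis polynomial
#' \eqn{b_k(m, x) = \binom{m}{k} x^k (1-x)^{m-k}} on \eqn{[0,1]}.
#' Computation goes through the binomial probability mass function, which
#' uses logarithmic binomial coefficients and so stays finite for degrees
#' in the hundreds.
#'
#' @param m nonnegative integer degree.
#' @param k integer index, `0 <= k <= m` (vectorised).
#' @param x evaluation points in \eqn{[0,1]} (vectorised).
#' @return Numeric vector of basis values; for fixed `x` the values over
#'   `k = 0:m` sum to 1.
#' @examples
#' bernstein_basis(2, 1, 0.5)      # 0.5
#' sum(bernstein_basis(5, 0:5, 0.3))  # 1
#' @export
bernstein_basis <- function(m, k, x) {
  if (length(m) != 1L || m < 0 || m != floor(m))
    stop("'m' must be a single nonnegative integer", call. = FALSE)
  if (any(k < 0) || any(k > m) || any(k != floor(k)))
    stop("'k' must be integer(s) in 0..m", call. = FALSE)
  if (any(x < 0) || any(x > 1))
    stop("'x' must lie in [0, 1]", call. = FALSE)
  stats::dbinom(k, size = m, prob = x)
}

#' Empirical distribution function
#'
#' \eqn{F_n(t) = \#\{X_i \le t\}/n}: right-continuous, counting with
#' "less than or equal".
#'
#' @param sample a [unit_sample] (or numeric vector coerced to one).
#' @param t evaluation points (any reals; vectorised).
#' @return Values of the empirical CDF in \eqn{[0,1]}.
#' @examples
#' empirical_cdf(unit_sample(c(0.2, 0.5, 0.8)), 0.5)  # 2/3
#' @export
empirical_cdf <- function(sample, t) {
  sample <- as_unit_sample(sample)
  vapply(t, function(ti) sum(sample$values <= ti), numeric(1)) / sample$n
}

#' Vitale's Bernstein-polynomial density estimator
#'
#' The estimator smooths the empirical CDF with the Bernstein basis:
#' \deqn{\tilde f_{1,n,m}(x) = m \sum_{k=0}^{m-1}
#'   \{F_n((k+1)/m) - F_n(k/m)\}\, b_k(m-1, x),}
#' a mixture of Beta(k+1, m-k) densities with weights given by
#' empirical-CDF increments on the grid \eqn{k/m}.
#'
#' @param sample a [unit_sample] or numeric vector on \eqn{[0,1]}.
#' @param m positive integer degree.
#' @return An object of class `vitale_fit` with fields `m`, `weights`
#'   (length `m`, summing to \eqn{1 - F_n(0)}) and `n`.
#' @seealso [evaluate_vitale()], [fit_shrinkage()]
#' @examples
#' fit <- fit_vitale(c(0.2, 0.5, 0.8), m = 2)
#' fit$weights                     # 2/3, 1/3
#' evaluate_vitale(fit, 0)         # 4/3
#' @export
fit_vitale <- function(sample, m) {
  sample <- as_unit_sample(sample)
  if (length(m) != 1L || m < 1 || m != floor(m))
    stop("'m' must be a single positive integer", call. = FALSE)
  Fn <- empirical_cdf(sample, (0:m) / m)
  structure(list(m = as.integer(m), weights = diff(Fn), n = sample$n),
            class = "vitale_fit")
}

#' Evaluate a Vitale density estimate
#'
#' @param est a `vitale_fit` from [fit_vitale()].
#' @param x evaluation points in \eqn{[0,1]} (vectorised).
#' @return Nonnegative density values
#'   \eqn{m \sum_k w_k b_k(m-1, x) = \sum_k w_k \mathrm{Beta}(k+1, m-k)(x)}.
#' @export
evaluate_vitale <- function(est, x) {
  stopifnot(inherits(est, "vitale_fit"))
  if (any(x < 0) || any(x > 1))
    stop("'x' must lie in [0, 1]", call. = FALSE)
  m <- est$m
  # rows: basis index k = 0..m-1; Beta(k+1, m-k) densities
  B <- vapply(seq_len(m), function(k1) stats::dbeta(x, k1, m - k1 + 1),
              numeric(length(x)))
  if (length(x) == 1L) B <- matrix(B, nrow = 1L)
  drop(B %*% est$weights)
}

#' @export
print.vitale_fit <- function(x, ...) {
  cat("Vitale Bernstein density estimate: m =", x$m, " n =", x$n,
      sprintf(" sum(weights) = %.6f\n", sum(x$weights)))
  invisible(x)
}

#' Bernstein-mixture density estimator fitted by EM
#'
#' Fits the parametric Bernstein-mixture model
#' \eqn{f_B(x; p) = \sum_{i=0}^{m} p_i B_{mi}(x)} with
#' \eqn{B_{mi}(x) = (m+1) b_i(m, x)} (a Beta(i+1, m-i+1) density) and
#' simplex weights \eqn{p}, by the EM fixed-point iteration
#' \deqn{p_i^{(s+1)} = \frac1n \sum_j
#'   \frac{p_i^{(s)} B_{mi}(x_j)}{\sum_k p_k^{(s)} B_{mk}(x_j)}.}
#' The observed log-likelihood is non-decreasing along the iteration.
#'
#' @param sample a [unit_sample] or numeric vector on \eqn{[0,1]}.
#' @param m nonnegative integer degree (the mixture has `m + 1`
#'   components indexed `0..m`).
#' @param p0 initial simplex vector of length `m + 1`; default uniform.
#' @param tol convergence tolerance on the max-abs change in `p`.
#' @param max_iter iteration cap.
#' @return An object of class `guan_fit`: fields `m`, `p` (simplex of
#'   length `m + 1`), `loglik` (trace, one entry per iteration),
#'   `iterations`, `converged`.
#' @seealso [evaluate_guan()]
#' @examples
#' fit <- fit_guan(c(0.25, 0.75), m = 1)
#' fit$p
#' @export
fit_guan <- function(sample, m, p0 = NULL, tol = 1e-8, max_iter = 500L) {
  sample <- as_unit_sample(sample)
  if (length(m) != 1L || m < 0 || m != floor(m))
    stop("'m' must be a single nonnegative integer", call. = FALSE)
  if (is.null(p0)) p0 <- rep(1 / (m + 1), m + 1)
  if (length(p0) != m + 1 || any(p0 < 0) || abs(sum(p0) - 1) > 1e-8)
    stop("'p0' must be a probability vector of length m + 1", call. = FALSE)
  x <- sample$values
  n <- sample$n
  # B[j, i+1] = (m+1) * b_i(m, x_j) = Beta(i+1, m-i+1) density at x_j
  B <- vapply(0:m, function(i) stats::dbeta(x, i + 1, m - i + 1),
              numeric(n))
  if (n == 1L) B <- matrix(B, nrow = 1L)
  p <- p0
  ll <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    mix <- drop(B %*% p)
    if (any(mix <= 0))
      stop("mixture density vanished at an observation; EM cannot proceed",
           call. = FALSE)
    ll <- c(ll, sum(log(mix)))
    p_new <- colMeans(B * rep(p, each = n) / mix)
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(m = as.integer(m), p = p, loglik = ll,
                 iterations = iter, converged = converged),
            class = "guan_fit")
}

#' Evaluate a Bernstein-mixture density estimate
#'
#' @param est a `guan_fit` from [fit_guan()].
#' @param x evaluation points in \eqn{[0,1]} (vectorised).
#' @return Density values \eqn{\sum_i p_i (m+1) b_i(m, x)}.
#' @export
evaluate_guan <- function(est, x) {
  stopifnot(inherits(est, "guan_fit"))
  if (any(x < 0) || any(x > 1))
    stop("'x' must lie in [0, 1]", call. = FALSE)
  m <- est$m
  B <- vapply(0:m, function(i) stats::dbeta(x, i + 1, m - i + 1),
              numeric(length(x)))
  if (length(x) == 1L) B <- matrix(B, nrow = 1L)
  drop(B %*% est$p)
}

#' @export
print.guan_fit <- function(x, ...) {
  cat("Bernstein-mixture density estimate (EM): m =", x$m,
      " iterations =", x$iterations,
      if (x$converged) "(converged)\n" else "(max_iter reached)\n")
  invisible(x)
}
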