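# Univariate finite Gaussian mixture fitted by EM, with gap-statistic
# selection of the number of components.  The mixture is the parametric
# component of the shrinkage estimator; it may be fitted on the
# unit-interval scale or on the data's native scale (see fit_shrinkage).

DENSITY_FLOOR <- 1e-300   # avoids 0/0 in posterior denominators
VARIANCE_FLOOR <- 1e-6    # sigma^2 lower bound; prevents component collapse

#' Construct Gaussian mixture parameters
#'
#' @param pi mixing proportions (simplex vector of length K).
#' @param mu component means.
#' @param sigma component standard deviations (all positive).
#' @return An object of class `gmm_params`.
#' @export
gmm_params <- function(pi, mu, sigma) {
  K <- length(pi)
  if (length(mu) != K || length(sigma) != K)
    stop("'pi', 'mu' and 'sigma' must have equal length", call. = FALSE)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("'pi' must be a probability vector", call. = FALSE)
  if (any(sigma <= 0))
    stop("'sigma' must be positive", call. = FALSE)
  structure(list(K = K, pi = as.numeric(pi), mu = as.numeric(mu),
                 sigma = as.numeric(sigma)),
            class = "gmm_params")
}

#' @export
print.gmm_params <- function(x, ...) {
  cat("Gaussian mixture,", x$K, "component(s):\n")
  print(data.frame(pi = x$pi, mu = x$mu, sigma = x$sigma), row.names = TRUE)
  invisible(x)
}

#' Gaussian mixture density
#'
#' \eqn{g(x) = \sum_k \pi_k N(\mu_k, \sigma_k)(x)}.
#'
#' @param params a `gmm_params` (or `gmm_fit`).
#' @param x evaluation points (any reals; vectorised).
#' @return Nonnegative density values.
#' @examples
#' gmm_density(gmm_params(1, 0, 1), 0)  # dnorm(0)
#' @export
gmm_density <- function(params, x) {
  p <- as_gmm_params(params)
  out <- numeric(length(x))
  for (k in seq_len(p$K))
    out <- out + p$pi[k] * stats::dnorm(x, p$mu[k], p$sigma[k])
  out
}

as_gmm_params <- function(params) {
  if (inherits(params, "gmm_fit")) return(params$params)
  stopifnot(inherits(params, "gmm_params"))
  params
}

#' EM E-step: posterior component responsibilities
#'
#' \eqn{\tau_{ij} = \pi_j N(\mu_j,\sigma_j)(X_i) /
#' \sum_h \pi_h N(\mu_h,\sigma_h)(X_i)}.
#'
#' @param params a `gmm_params`.
#' @param x numeric data vector.
#' @return An `n` by `K` matrix whose rows sum to 1.
#' @export
gmm_e_step <- function(params, x) {
  p <- as_gmm_params(params)
  if (inherits(x, "unit_sample")) x <- x$values
  dens <- vapply(seq_len(p$K),
                 function(k) p$pi[k] * stats::dnorm(x, p$mu[k], p$sigma[k]),
                 numeric(length(x)))
  if (length(x) == 1L) dens <- matrix(dens, nrow = 1L)
  tot <- pmax(rowSums(dens), DENSITY_FLOOR)
  dens / tot
}

#' EM M-step: update mixture parameters from responsibilities
#'
#' \eqn{\pi_j = \bar\tau_{\cdot j}}, \eqn{\mu_j} the responsibility-
#' weighted mean, \eqn{\sigma_j^2} the responsibility-weighted variance
#' (floored at `1e-6` to prevent degenerate components).
#'
#' @param tau responsibility matrix (rows sum to 1).
#' @param x numeric data vector, `length(x) == nrow(tau)`.
#' @return A `gmm_params`.
#' @export
gmm_m_step <- function(tau, x) {
  if (inherits(x, "unit_sample")) x <- x$values
  tau <- as.matrix(tau)
  if (nrow(tau) != length(x))
    stop("'tau' must have one row per observation", call. = FALSE)
  nk <- colSums(tau)
  if (any(nk <= 0))
    stop("a mixture component has zero total responsibility", call. = FALSE)
  mu <- drop(crossprod(tau, x)) / nk
  sig2 <- vapply(seq_along(nk),
                 function(j) sum(tau[, j] * (x - mu[j])^2) / nk[j],
                 numeric(1))
  gmm_params(pi = nk / length(x), mu = mu,
             sigma = sqrt(pmax(sig2, VARIANCE_FLOOR)))
}

gmm_loglik <- function(params, x) {
  sum(log(pmax(gmm_density(params, x), DENSITY_FLOOR)))
}

#' Fit a univariate Gaussian mixture by EM
#'
#' Alternates [gmm_e_step()] and [gmm_m_step()] until the maximum
#' absolute parameter change falls below `tol` or `max_iter` is reached.
#' Means are initialised by k-means on the data (seeded, so fits are
#' reproducible), proportions start equal and standard deviations start
#' at the pooled value.
#'
#' @param x numeric data vector (or [unit_sample]).
#' @param K number of components, `K <= length(x)`; `"auto"` selects K
#'   by the gap statistic ([select_K_gap()]).
#' @param tol convergence tolerance on the max-abs parameter change.
#' @param max_iter iteration cap.
#' @param seed integer seed for the initialisation (and for `"auto"` K
#'   selection).
#' @return An object of class `gmm_fit`: fields `params` (a
#'   `gmm_params`), `K`, `loglik` (trace), `iterations`, `converged`.
#' @examples
#' x <- c(rnorm(50, 0.2, 0.03), rnorm(50, 0.8, 0.03))
#' fit_gmm_em(x, K = 2, seed = 1)$params
#' @export
fit_gmm_em <- function(x, K, tol = 1e-6, max_iter = 500L, seed = 1L) {
  if (inherits(x, "unit_sample")) x <- x$values
  if (identical(K, "auto")) K <- select_K_gap(x, seed = seed)
  if (length(K) != 1L || K < 1 || K != floor(K))
    stop("'K' must be a single positive integer or \"auto\"", call. = FALSE)
  n <- length(x)
  if (n < K)
    stop("need at least K observations to fit K components", call. = FALSE)

  params <- with_seed(seed, gmm_init(x, K))
  ll <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    tau <- gmm_e_step(params, x)
    new <- gmm_m_step(tau, x)
    ll <- c(ll, gmm_loglik(new, x))
    delta <- max(abs(c(new$pi - params$pi, new$mu - params$mu,
                       new$sigma - params$sigma)))
    params <- new
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(params = params, K = params$K, loglik = ll,
                 iterations = iter, converged = converged),
            class = "gmm_fit")
}

# k-means seeding of means; equal proportions; pooled sd.
gmm_init <- function(x, K) {
  if (K == 1L) {
    mu <- mean(x)
  } else if (length(unique(x)) < K) {
    mu <- seq(min(x), max(x), length.out = K)
  } else {
    km <- stats::kmeans(x, centers = K, nstart = 5, iter.max = 50)
    mu <- sort(as.numeric(km$centers))
  }
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) s <- 1
  gmm_params(pi = rep(1 / K, K), mu = mu,
             sigma = rep(max(s, sqrt(VARIANCE_FLOOR)), K))
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("Gaussian mixture fit (EM):", x$K, "component(s),",
      x$iterations, "iteration(s),",
      if (x$converged) "converged\n" else "max_iter reached\n")
  print(x$params)
  invisible(x)
}

#' Select the number of mixture components by the gap statistic
#'
#' Compares the log within-cluster dispersion of k-means clusterings of
#' the data against its expectation under `B` uniform reference sets on
#' the data range, and returns the smallest `k` with
#' \eqn{\mathrm{Gap}(k) \ge \mathrm{Gap}(k+1) - s_{k+1}}.
#'
#' @param x numeric data vector (or [unit_sample]).
#' @param K_max largest number of clusters considered (reduced to the
#'   number of distinct observations, with a warning, if larger).
#' @param B number of uniform reference data sets.
#' @param seed integer seed (reference draws and k-means restarts).
#' @return The selected number of clusters (positive integer).
#' @examples
#' x <- c(rnorm(100, 0.1, 0.01), rnorm(100, 0.9, 0.01))
#' select_K_gap(x, seed = 1)  # 2
#' @export
select_K_gap <- function(x, K_max = 10L, B = 50L, seed = 1L) {
  if (inherits(x, "unit_sample")) x <- x$values
  if (K_max < 1 || B < 1)
    stop("'K_max' and 'B' must be at least 1", call. = FALSE)
  n_distinct <- length(unique(x))
  if (n_distinct == 1L) return(1L)
  if (K_max >= n_distinct) {
    warning("'K_max' larger than the number of distinct observations; reduced",
            call. = FALSE)
    K_max <- n_distinct - 1L
  }
  if (K_max == 1L) return(1L)
  km_fun <- function(x, k) {
    if (k == 1L)
      list(cluster = rep(1L, nrow(as.matrix(x))))
    else
      suppressWarnings(stats::kmeans(x, centers = k, nstart = 10,
                                     iter.max = 50))
  }
  gap <- with_seed(seed,
    cluster::clusGap(matrix(x, ncol = 1), FUNcluster = km_fun,
                     K.max = K_max, B = B, spaceH0 = "original",
                     verbose = FALSE))
  tab <- gap$Tab
  as.integer(cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                            method = "Tibs2001SEmax"))
}

# Run 'expr' under a temporary RNG state seeded with 'seed'; the caller's
# RNG stream is left untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
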