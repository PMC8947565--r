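#' Gaussian kernel density estimator
#'
#' The standard kernel estimator
#' \eqn{\hat f_n(x) = (nh)^{-1} \sum_i \phi\{(x - X_i)/h\}} with the
#' standard normal kernel \eqn{\phi} and fixed bandwidth \eqn{h}.  No
#' boundary correction is applied: on a compact support the estimator
#' leaks mass past the endpoints, which is precisely the boundary bias
#' the shrinkage estimator is designed to avoid (see [kde_mass_unit()]).
#'
#' @param sample a [unit_sample] or numeric vector.
#' @param h positive bandwidth.
#' @return An object of class `kde_fit` with fields `values`, `n`, `h`.
#' @examples
#' fit <- fit_kernel(c(0.2, 0.5, 0.8), h = 0.1)
#' evaluate_kernel(fit, 0.5)
#' @export
fit_kernel <- function(sample, h) {
  sample <- as_unit_sample(sample)
  if (length(h) != 1L || !is.finite(h) || h <= 0)
    stop("'h' must be a single positive number", call. = FALSE)
  structure(list(values = sample$values, n = sample$n, h = h),
            class = "kde_fit")
}

#' Evaluate a Gaussian kernel density estimate
#'
#' @param est a `kde_fit` from [fit_kernel()].
#' @param x evaluation points (any reals; vectorised).
#' @return Nonnegative density values; the integral over the whole real
#'   line is 1, but the integral over \eqn{[0,1]} is below 1 for samples
#'   near the boundary.
#' @export
evaluate_kernel <- function(est, x) {
  stopifnot(inherits(est, "kde_fit"))
  vapply(x, function(xi)
    mean(stats::dnorm((xi - est$values) / est$h)) / est$h,
    numeric(1))
}

#' Mass of a kernel estimate on the unit interval
#'
#' Closed form via the normal CDF:
#' \eqn{n^{-1} \sum_i \{\Phi((1 - X_i)/h) - \Phi(-X_i/h)\}}.  Values
#' visibly below 1 quantify the boundary leakage of the uncorrected
#' kernel estimator.
#'
#' @param est a `kde_fit`.
#' @return The probability mass the estimate places on \eqn{[0,1]}.
#' @export
kde_mass_unit <- function(est) {
  stopifnot(inherits(est, "kde_fit"))
  mean(stats::pnorm((1 - est$values) / est$h) -
       stats::pnorm((0 - est$values) / est$h))
}

#' @export
print.kde_fit <- function(x, ...) {
  cat("Gaussian kernel density estimate: n =", x$n, " h =", x$h, "\n")
  invisible(x)
}
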