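# Support transformations.  Every estimator in the package works on
# [0,1]; data on an interval [a,b], on the real line, or on the positive
# half line are mapped there first, and true densities are carried along
# by the change of variables so that integrated errors are computed on
# the common unit scale.

#' Declare the support of a sample
#'
#' @param kind `"interval"`, `"real_line"` or `"positive_half_line"`.
#' @param a,b interval endpoints (required when `kind = "interval"`,
#'   with `a < b`; ignored otherwise).
#' @return An object of class `support_spec`.
#' @examples
#' support_spec("interval", 0, 605)
#' support_spec("real_line")
#' @export
support_spec <- function(kind = c("interval", "real_line", "positive_half_line"),
                         a = NULL, b = NULL) {
  kind <- match.arg(kind)
  if (kind == "interval") {
    if (is.null(a) || is.null(b) || !is.finite(a) || !is.finite(b) || a >= b)
      stop("interval support requires finite 'a' < 'b'", call. = FALSE)
  } else {
    a <- b <- NULL
  }
  structure(list(kind = kind, a = a, b = b), class = "support_spec")
}

#' @export
print.support_spec <- function(x, ...) {
  cat("Support:",
      switch(x$kind,
             interval = sprintf("[%g, %g]", x$a, x$b),
             real_line = "(-Inf, Inf)",
             positive_half_line = "[0, Inf)"), "\n")
  invisible(x)
}

#' Map observations to the unit interval
#'
#' Interval \eqn{[a,b]}: \eqn{y = (x-a)/(b-a)}.  Real line:
#' \eqn{y = 1/2 + \arctan(x)/\pi}.  Positive half line:
#' \eqn{y = x/(1+x)}.  The two unbounded maps send the support into the
#' open interval \eqn{(0,1)}.
#'
#' @param values numeric vector on the declared support.
#' @param spec a [support_spec].
#' @return A [unit_sample].
#' @examples
#' to_unit(0, support_spec("real_line"))$values       # 0.5
#' to_unit(1, support_spec("positive_half_line"))$values  # 0.5
#' @export
to_unit <- function(values, spec) {
  stopifnot(inherits(spec, "support_spec"))
  bad <- switch(spec$kind,
                interval = which(values < spec$a | values > spec$b),
                real_line = integer(0),
                positive_half_line = which(values < 0))
  if (length(bad))
    stop("value(s) outside the declared support at index ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  y <- switch(spec$kind,
              interval = (values - spec$a) / (spec$b - spec$a),
              real_line = 0.5 + atan(values) / pi,
              positive_half_line = values / (1 + values))
  suppressWarnings(unit_sample(y))
}

#' Map unit-interval points back to the native support
#'
#' Exact inverse of [to_unit()].  For the unbounded supports the
#' endpoints 0 and 1 have no finite preimage and raise an error.
#'
#' @param values numeric vector in \eqn{[0,1]} (strictly inside
#'   \eqn{(0,1)} for unbounded supports).
#' @param spec a [support_spec].
#' @return Numeric vector on the native support.
#' @export
from_unit <- function(values, spec) {
  stopifnot(inherits(spec, "support_spec"))
  if (any(values < 0) || any(values > 1))
    stop("'values' must lie in [0, 1]", call. = FALSE)
  if (spec$kind != "interval" && any(values == 0 | values == 1))
    stop("0 and 1 have no finite preimage for an unbounded support",
         call. = FALSE)
  switch(spec$kind,
         interval = spec$a + values * (spec$b - spec$a),
         real_line = tan(pi * (values - 0.5)),
         positive_half_line = values / (1 - values))
}

#' Transform a density to the unit-interval scale
#'
#' Given a density \eqn{f_X} on the native support, returns the density
#' of the transformed variable \eqn{Y = T(X)} on \eqn{(0,1)}:
#' \eqn{f_Y(y) = f_X(T^{-1}(y)) \, |dT^{-1}/dy|}.  The Jacobian is
#' \eqn{b-a} (interval), \eqn{\pi(1+x^2)} (real line) and
#' \eqn{(1-y)^{-2}} (half line).
#'
#' @param pdf function: the density on the native support.
#' @param spec a [support_spec].
#' @return A vectorised function on \eqn{(0,1)} integrating to 1.
#' @examples
#' f <- transform_density(function(x) stats::dcauchy(x), support_spec("real_line"))
#' f(c(0.2, 0.7))  # constant 1: the Cauchy cancels the Jacobian
#' @export
transform_density <- function(pdf, spec) {
  stopifnot(is.function(pdf), inherits(spec, "support_spec"))
  switch(spec$kind,
         interval = function(y)
           pdf(spec$a + y * (spec$b - spec$a)) * (spec$b - spec$a),
         real_line = function(y) {
           x <- tan(pi * (y - 0.5))
           pdf(x) * pi * (1 + x^2)
         },
         positive_half_line = function(y)
           pdf(y / (1 - y)) / (1 - y)^2)
}

#' Data-driven bounds for an effectively infinite support
#'
#' Chooses an interval \eqn{[a,b]} strictly containing the sample, with
#' overshoot of order \eqn{1/n} of the sample range on each side, so
#' that the mass beyond the bounds is of order \eqn{O(n^{-1})}.  Useful
#' when data on an unbounded support are to be treated with the interval
#' map.
#'
#' @param values numeric sample.
#' @param n sample size used for the overshoot (default `length(values)`).
#' @return `c(a, b)` with `a < min(values)` and `b > max(values)`.
#' @examples
#' data_driven_bounds(c(0, 1))  # -0.5, 1.5
#' @export
data_driven_bounds <- function(values, n = length(values)) {
  if (n < 2)
    stop("need at least two observations", call. = FALSE)
  lo <- min(values); hi <- max(values)
  r <- hi - lo
  if (r == 0) {
    warning("constant sample; widening by a fixed fraction of |x|",
            call. = FALSE)
    pad <- 0.1 * max(abs(lo), 1)
    return(c(lo - pad, hi + pad))
  }
  c(lo - r / n, hi + r / n)
}
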