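#' Construct a sample on the unit interval
#'
#' Estimators in this package operate on observations that live on
#' \eqn{[0,1]}; data on other supports are first mapped there with
#' [to_unit()].  `unit_sample()` validates and wraps a numeric vector,
#' `as_unit_sample()` coerces vectors or existing objects.
#'
#' Observations exactly equal to 0 are legal but remove mass from the
#' Vitale weight vector (the empirical CDF at 0 becomes positive), so
#' they trigger a warning.
#'
#' @param values numeric vector with all elements in \eqn{[0,1]}.
#' @return An object of class `unit_sample`: a list with elements
#'   `values` and `n`.
#' @examples
#' s <- unit_sample(c(0.2, 0.5, 0.8))
#' s$n
#' @export
unit_sample <- function(values) {
  if (!is.numeric(values) || length(values) < 1L)
    stop("'values' must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(values))
    stop("'values' must not contain NA", call. = FALSE)
  if (any(values < 0) || any(values > 1))
    stop("all values must lie in [0, 1]; transform the data first (see to_unit())",
         call. = FALSE)
  if (any(values == 0))
    warning("sample contains observations exactly at 0; ",
            "they remove mass from the Vitale weights", call. = FALSE)
  structure(list(values = as.numeric(values), n = length(values)),
            class = "unit_sample")
}

#' @rdname unit_sample
#' @param x object to coerce.
#' @export
as_unit_sample <- function(x) {
  if (inherits(x, "unit_sample")) return(x)
  unit_sample(x)
}

#' @export
print.unit_sample <- function(x, ...) {
  cat("Unit-interval sample: n =", x$n,
      sprintf("range = [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}
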