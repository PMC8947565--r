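# Shared helpers: independent brute-force oracles and small utilities.

# Mass of a density function on [lo, hi] by fine trapezoid quadrature.
quad_mass <- function(f, lo = 0, hi = 1, n = 20001L) {
  x <- seq(lo, hi, length.out = n)
  pracma::trapz(x, f(x))
}

# Brute-force Vitale oracle: weighted sum of Beta(k+1, m-k) densities,
# built from factorials, independently of the package's basis code.
vitale_oracle <- function(weights, m, x) {
  out <- numeric(length(x))
  for (k in 0:(m - 1)) {
    const <- factorial(m) / (factorial(k) * factorial(m - k - 1))
    out <- out + weights[k + 1] * const * x^k * (1 - x)^(m - k - 1)
  }
  out
}

# Observed log-likelihood of a lambda-mixture of two fixed densities.
mix_loglik <- function(lam, f1v, f2v) sum(log(lam * f1v + (1 - lam) * f2v))
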