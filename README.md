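# shrinkdens

Semi-parametric density estimation on a bounded interval by a
**shrinkage combination of a Bernstein-polynomial estimator and a
finite Gaussian mixture**.

Kernel density estimators are biased at the endpoints of a compactly
supported density and leak probability mass past them.  Vitale's
Bernstein-polynomial estimator

> f̃₁,ₙ,ₘ(x) = m Σₖ { Fₙ((k+1)/m) − Fₙ(k/m) } bₖ(m−1, x),  bₖ(m,x) = C(m,k) xᵏ(1−x)^(m−k)

is boundary-safe but purely nonparametric; a Gaussian mixture
f̃₂,ₙ = Σ π̂ₖ N(μ̂ₖ, σ̂ₖ) fitted by EM has no boundary problem but
carries model bias.  The package estimates

> f̂ₙ,ₘ(x) = λ̂ · f̃₁,ₙ,ₘ(x) + (1 − λ̂) · f̃₂,ₙ(x),

where the shrinkage weight λ̂ ∈ [0,1] is itself estimated by an EM
iteration that treats the component membership of each observation as
a hidden Bernoulli label: E-step
τ̄ᵢ₁ = λf̃₁(Xᵢ) / {λf̃₁(Xᵢ) + (1−λ)f̃₂(Xᵢ)}, M-step λ ← mean(τ̄·₁).
The package is aimed at statisticians and epidemiological modellers
estimating densities of bounded or half-line quantities (daily case
counts, sighting distances, proportions) where boundary behaviour
matters.

Also included: the Gaussian kernel and Bernstein-mixture (EM)
comparator estimators, support transforms (interval, real line via
arctan, half line via x/(1+x)) with change-of-variables density
transport, ISE/IAE/KL error metrics, pointwise asymptotic confidence
intervals, a seeded Monte-Carlo benchmark over six test densities, and
a file-based front end with a thin command-line wrapper
(`inst/cli/shrinkdens.R`).

## Worked example

```r
library(shrinkdens)
set.seed(42)
x <- rbeta(200, 3, 9)                       # bounded support, mode near 0.2
fit <- fit_shrinkage(x, m = 30, K = "auto", seed = 1)
fit
#> Shrinkage density estimate: lambda = 0.5010, m = 30, n = 200
#>   parametric component: Gaussian mixture, K = 1
#>   NOTE: parametric component has mass 0.9865 on [0,1];
#>   the combined estimate integrates to less than 1
```

The weight λ̂ ≈ 0.50 says the sample is explained about equally well
by the degree-30 Bernstein fit and the single-Gaussian fit; the note
flags that the Gaussian tail spills slightly past the support.
Pointwise 95% confidence bands and the error against the known truth:

```r
asymptotic_ci(fit, c(0.1, 0.5, 0.9))
#>     x       fit      lower     upper
#> 1 0.1 1.864e+00  1.825e+00 1.903e+00
#> 2 0.5 4.155e-01  4.011e-01 4.299e-01
#> 3 0.9 2.427e-07 -1.393e-05 1.442e-05
ise(function(z) evaluate_shrinkage(fit, z), function(z) dbeta(z, 3, 9))
#> [1] 0.0206519
```

For files instead of vectors:

```sh
Rscript inst/cli/shrinkdens.R simulate --density a --n 200 --seed 7 --output sample.csv
Rscript inst/cli/shrinkdens.R fit --input sample.csv --support interval:0,1 \
    --json report.json --csv density.csv
```

The benchmark harness (`run_benchmark()`, or the `benchmark` CLI
command) draws seeded samples from six catalogue densities, applies
the 2/3–1/3 train/test protocol with oracle ISE tuning of the
Bernstein degree and kernel bandwidth, and averages ISE/IAE/KL per
estimator.  See the vignette
(`vignettes/shrinkage-density-estimation.Rmd`) for the model, the
numerical choices and the harness design.

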