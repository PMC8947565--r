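Package: shrinkdens
Title: Semi-Parametric Shrinkage Density Estimation with Bernstein
    Polynomials and Gaussian Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Density estimation on a bounded interval by a shrinkage
    (convex) combination of the Vitale Bernstein-polynomial estimator and
    a finite Gaussian mixture fitted by the EM algorithm.  The mixing
    weight is itself estimated by a dedicated EM step, so the estimator
    adapts between the nonparametric and the parametric component and
    alleviates the boundary bias of kernel density estimators on compact
    supports.  Includes the Gaussian kernel and Bernstein-mixture
    comparator estimators, support transformations for data on the real
    or positive half line, integrated-error metrics (ISE, IAE,
    Kullback-Leibler divergence), asymptotic confidence intervals, and a
    seeded Monte-Carlo benchmark harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
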