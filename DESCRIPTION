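Package: bfamet
Title: Bayesian Factor Analytic Models for Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the Bayesian factor analytic (BFA) mixed model to
    multi-environment trial phenotype data by Gibbs sampling. The genetic
    covariance across environments is parameterized through its spectral
    decomposition (ordered singular values and orthonormal eigenvectors),
    eigenvectors are sampled in a Gram-Schmidt-corrected subspace so every
    draw satisfies the orthonormality constraints, and per-environment
    residual variances are heterogeneous. Includes posterior summaries
    (Chen-Shao style MAP, HPD intervals, convergence diagnostics), biplot
    coordinates with bivariate credibility regions, cell-deletion
    cross-validation with PRESS and predictive correlation, AICM-based
    selection of the number of factors, and a simulator for trials with
    known genetic structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    coda,
    lme4,
    truncnorm
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    jsonlite,
    optparse
Config/testthat/edition: 3
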