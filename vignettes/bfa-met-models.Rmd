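---
title: "Bayesian factor analytic models for multi-environment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian factor analytic models for multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfamet)
```

## The model

Multi-environment trials (MET) evaluate a common panel of `m` genotypes in `p`
environments, usually in `q` replicated blocks per environment. The quantity
of interest is the genotype-by-environment interaction (GEI): how differently
genotypes respond across environments, and which genotypes are stable. The
factor analytic (FA) mixed model summarizes the genetic covariance across
environments as

$$\Sigma = \Gamma\Gamma' + \Psi,$$

with a `p x k` loading matrix $\Gamma$ and diagonal specific variances
$\Psi$. This package fits the Bayesian version of that model with the loading
matrix written through the spectral decomposition of $\Sigma - \Psi$:

$$\Gamma = [\lambda_1\alpha_1, \dots, \lambda_k\alpha_k], \qquad
\lambda_1 \ge \dots \ge \lambda_k \ge 0, \qquad \alpha_i'\alpha_j = \delta_{ij},$$

so the model mean for the `n` plot records is, in summation form,

$$\theta = X_1\beta + \sum_{j=1}^{k} \lambda_j\,
\mathrm{diag}(X_2\alpha_j)\, Z_f f_j + Z\delta,$$

where $\beta$ are fixed environment-block cell means, $f_j$ are
standard-normal genotype scores, $\delta$ are cell-specific genetic effects
with $\mathrm{Var}(\delta_{ge}) = \psi_e$, and residuals are Gaussian with a
per-environment variance $\sigma^2_{e}$ (heterogeneous across environments,
homogeneous within). Because the parameterization enforces orthonormal
eigenvectors and ordered nonnegative singular values at every draw, the model
is identified without rotation and specific variances can never go negative
(no Heywood cases). With `k = p` ("full rank") the specific effects are
identically zero and $\Sigma$ is unstructured.

The genotype main effect is deliberately confounded with the interaction
(G + GE): the first factor then tends to carry the marginal genotype signal
with all-positive environment loadings, and the biplot of the first two axes
reads like a GGE-biplot.

## Sampling scheme

All full conditionals are conjugate: Gaussian for $\beta$, each $f$ column
block, and $\delta$; truncated Gaussian for each $\lambda_j$; scaled inverse
chi-squared for $\psi_e$ and $\sigma^2_e$. Two blocks need care:

* **Singular values.** The joint constraint
  $\lambda_1 \ge \dots \ge \lambda_k \ge 0$ is kept invariant by truncating
  each coordinate's Gaussian conditional to
  $[\lambda_{j+1}, \lambda_{j-1}]$ (0 below the last factor, unbounded above
  the first). Draws use `truncnorm::rtruncnorm`, which is robust when the
  conditional mean sits far outside the bounds.
* **Eigenvectors.** The Gaussian conditional for $\alpha_j$ does not respect
  unit norm or orthogonality. The draw is therefore made in the
  *corrected subspace*: with $H_s$ the eigenvectors already updated in the
  scan, an orthonormal complement $H_k$ is built (QR-based Gram-Schmidt
  completion, `gram_schmidt_complement()`), the $(p-s)$-dimensional Gaussian
  $\tilde\alpha \sim N\!\big(H_k'(\Delta'R^{-1}\Delta)^{-1}\Delta'R^{-1}A,\;
  (H_k'(\Delta'R^{-1}\Delta)H_k)^{-1}\big)$ is drawn, normalized (the
  back-transformation preserves the norm, so normalizing before or after is
  equivalent), and mapped back as $\alpha_j = H_k\tilde\alpha$. Every draw is
  exactly unit-norm and orthogonal to its predecessors.

The scan order is $\beta$, $\lambda_{1..k}$, $\alpha_{1..k}$, $f$, $\delta$,
$\Psi$, $\sigma^2_e$, and partial residuals are recomputed from the current
state before each conditional rather than incrementally patched — correctness
over micro-optimization. The likelihood is invariant to a joint sign flip of
$(\alpha_j, f_j)$; retained draws are sign-aligned (the dominant coordinate of
each eigenvector's running posterior mean is made positive, flipping the
matching score column) so posterior means of loadings and scores are not
corrupted by sign switching. The alignment relabels retained copies only and
does not alter the chain's law.

### Numerical and design choices

* The printed conditionals for $\beta$ and $\lambda$ are flat-prior limits;
  the implementation includes the prior precision terms ($1/\sigma^2_\beta$,
  $1/\sigma^2_\lambda$, both $10^{-12}$ at the defaults), which is numerically
  identical at the defaults but keeps the conditionals proper under
  informative priors.
* The specific-effect conditional uses the residual covariance `R` in both
  kernel factors; the specific effect vector covers every genotype x
  environment cell (observed or not), so the $\psi_e$ update has degrees of
  freedom `m + nu_k` with the sum of squares over all `m` entries of the
  environment.
* Fixed effects use cell-means coding with one column per *occurring*
  environment-block cell: incomplete block designs never create empty,
  rank-deficient columns, and `dim(beta)` equals the number of used cells.
* Initialization: $\beta$ at cell means; eigenpairs of the covariance of the
  two-way residual-mean table give the starting $\lambda$ and $\alpha$; scores
  start at the table's projection onto those eigenvectors. A zero-score start
  would make the first $\lambda$ and $\alpha$ conditionals degenerate (their
  regressors vanish), so the projection start is used instead.
* Environments with fewer than two observations are refused: with the
  scale-invariant prior ($\nu_e = 0$) their residual-variance conditional
  would be improper or degenerate.
* A single seeded generator drives the whole run; identical inputs give
  bitwise-identical chains.

## Posterior summaries

`summary()` reports posterior means, standard deviations, an HPD-based mode
estimate (the midpoint of the shortest window holding 5% of the sorted draws
— the eigenvectors are orthonormal draw by draw, but their posterior mean is
not, so a mode-type point estimate is reported alongside), and shortest
contiguous 95% HPD intervals. `biplot_coordinates()` returns the loading
products $(\lambda_1\alpha_1, \lambda_2\alpha_2)$ per environment and score
pairs $(f_1, f_2)$ per genotype with bivariate 95% credibility regions: the
Euclidean distances of the draws to their coordinatewise posterior mean are
computed, the farthest 5% discarded, and the convex hull of the retained
points taken as the boundary. The hull stays faithful to the stated
distance-cutoff construction instead of assuming a Gaussian ellipse; distances
are unstandardized, as the construction prescribes. A region that excludes the
biplot origin flags a coordinate pair credibly different from zero.
Convergence diagnostics (Geweke, Heidelberger-Welch, Raftery-Lewis) wrap the
`coda` reference implementations behind small functions with explicit
degenerate-chain errors.

`variance_partition()` reports, at the posterior mean, geometric means over
environments of the genetic variance carried by the loadings
$\mathrm{diag}(\Gamma\Gamma')$, the total genetic variance
$\mathrm{diag}(\Gamma\Gamma' + \Psi)$, the specific variances and the residual
variances. For a full-rank fit the specific variances are identically zero,
so the loadings recover all of the genetic variance — a useful diagnostic
that the identification constraints are doing their job.

## Cross-validation and order selection

`make_cell_folds()` partitions the observed genotype x environment cells into
near-equal folds (10-, 3- and 2-fold correspond to 10%, 33% and 50% deletion);
all replicates of a deleted cell are withheld together, every environment
keeps at least one cell, and every genotype stays evaluated in at least one
environment. Infeasible requests fail with the limiting genotype named.
`run_cv()` refits the model per training set and predicts each deleted cell
by the posterior mean of (environment fixed effect averaged over its block
cells — the block of a deleted plot is undefined) + (factor contribution) +
(specific effect); predictions are scored against withheld cell means with
PRESS (mean squared form) and the Pearson correlation, per fold and pooled
(both are reported since either pooling convention appears in practice).
`select_k()` runs the same folds for every candidate order and adds
AICM $= 2(\bar\ell - s^2_\ell)$ from a full-data fit per order ($s^2_\ell$ the
N−1 sample variance of the retained log-likelihood draws; the highest AICM is
preferred, and criteria are allowed to disagree). AICM is reported on the raw
log-likelihood scale. `marginal_blups()` fits the baseline two-way mixed model
(fixed cells + a single random genotype effect) via `lme4` REML; the
regression of first-factor posterior-mean scores on these BLUPs is the
standard check that axis 1 carries the marginal genotype signal.

## The simulator

`simulate_met()` emulates a randomized complete block MET with three genotype
stability groups: positive-unstable and negative-unstable genotypes (nonzero
mean marginal effects, interaction variance 2) and stable genotypes (zero-mean
marginals, standard-Gaussian interactions), with heterogeneous per-environment
residual variances (defaults 0.546, 1.209, 4.690, 7.377, 9.026) and 20
genotypes (5/5/10) x 5 environments x 2 replicates. Each genotype's marginal
effect is itself a Gaussian realization (unit standard deviation by default)
around its group's mean, which defaults to ±2.5 trait units.

The group-mean magnitude is not a free dial: it is calibrated to the scale of
the reference design's printed first-axis loading products, whose squared norm
(about 20 across the five environments) matches the expected realized scale
$\lambda_1^2 = p\,(0.5\mu^2 + 1) + \bar v \approx 22$ at $\mu = 2.5$. The
design's companion heuristic — an expected predictive ceiling of about 0.82
from the intraclass correlation
$\sqrt{\mathrm{var}(u)/(\mathrm{var}(u)+\bar\sigma^2_e/q)}$ — would suggest a
somewhat smaller separation; the printed loading products were given
precedence because they directly record the realized genetic signal of the
dataset the predictive claims were made on, and the discrepancy is noted here
rather than split.

Environment and block fixed effects default to zero (they are nuisance
cells absorbed by $\beta$). The generator returns the realized truth
(marginal effects, interactions, per-environment realized noise variances,
the realized genetic covariance and its spectral loading products), so
recovery can be checked against the actually-drawn values rather than only
the population constants.

What the simulator does *not* emulate: incomplete-block layouts of real
trials (missingness is produced by cell deletion, not by design), spatial
field trends, pedigree or marker relatedness between genotypes, and
cross-environment correlation of the interaction deviations (interactions are
drawn independently per environment, so only the marginal component of a
genotype's effect is predictable in a deleted environment — passing
cross-validation bounds here says nothing about predicting correlated
environmental responses in real networks).

## Problem sizes used in the tests

The package's checks run at desk scale by choice: cross-validation refits use
6,000-iteration chains (1,000 burn-in, thinning 2) per fold — posterior-mean
predictions are stable well before the headline chain lengths needed for
tail quantiles; the multi-replicate coverage check uses 50 simulated trials
with 2,500-iteration chains; Monte-Carlo oracle checks of the conditionals
use 20,000-50,000 draws with tolerances expressed in Monte-Carlo standard
errors so the draw count only sets the resolution of the check.

## Known limitations

* Single-trait analysis only; no pedigree/kinship, no spatial row-column
  terms.
* The residual covariance is diagonal by environment; a dense (inverse
  Wishart) residual structure and sparse-loading priors are out of scope.
* The number of factors is selected by refitting candidates (PRESS/SE/AICM);
  there is no transdimensional sampler.
* The per-coordinate truncation of the singular values enforces the order
  constraint exactly but can mix slowly when two singular values are nearly
  tied.
* AICM differences between candidate orders are small by construction here:
  the identity $\Gamma\Gamma' = \Sigma - \Psi$ makes marginal likelihoods
  nearly equal across orders, so cross-validation criteria are usually more
  decisive than AICM.
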