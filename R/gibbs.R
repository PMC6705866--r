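#' Sampler configuration
#'
#' Chain-control quantities for [run_gibbs()]. The number of retained draws is
#' `floor((iterations - burn_in) / thin)`.
#'
#' @param k number of common factors (1..p). Forced to `p` when
#'   `full_rank = TRUE`.
#' @param iterations total Gibbs scans.
#' @param burn_in discarded initial scans.
#' @param thin keep-every interval.
#' @param seed RNG seed for the whole run.
#' @param full_rank fit the full-rank model (k = p, specific effects and
#'   variances identically zero, equivalent to an unstructured genetic
#'   covariance)?
#' @return An object of class `bfa_config`.
#' @export
bfa_config <- function(k, iterations, burn_in = 0, thin = 1, seed = 1,
                       full_rank = FALSE) {
  stopifnot(iterations > burn_in, burn_in >= 0, thin >= 1, k >= 1)
  structure(list(k = as.integer(k), iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), full_rank = isTRUE(full_rank)),
            class = "bfa_config")
}

#' Number of retained draws for given chain settings
#'
#' @param iterations,burn_in,thin chain-control quantities.
#' @return `floor((iterations - burn_in) / thin)`.
#' @export
n_retained <- function(iterations, burn_in, thin) {
  as.integer((iterations - burn_in) %/% thin)
}

# lightweight index bundle used by all conditional samplers
met_index <- function(data) {
  if (!is.null(data$idx)) return(data$idx)
  r <- data$records
  list(y = r$value, e = r$env_id, g = r$gen_id, eb = r$eb, ge = r$ge,
       n = data$n, m = data$m, p = data$p, n_eb = nrow(data$eb_cells),
       eb_env = data$eb_cells$env_id,
       cell_env = rep(seq_len(data$p), times = data$m),
       cnt_eb = tabulate(r$eb, nbins = nrow(data$eb_cells)),
       cnt_ge = tabulate(r$ge, nbins = data$m * data$p),
       n_env = tabulate(r$env_id, nbins = data$p))
}

# grouped sums over an index with a fixed number of groups
grouped_sum <- function(x, idx, ngroups) {
  out <- numeric(ngroups)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Initialize the sampler state from the data
#'
#' Fixed effects start at the environment-block cell means; the genotype x
#' environment table of residual means is formed, its sample covariance across
#' environments eigendecomposed, and the leading k eigenpairs give the starting
#' singular values (square roots of eigenvalues, clipped at zero, sorted) and
#' eigenvectors; factor scores start at the table's projection onto those
#' eigenvectors (so no conditional is degenerate at the first scan), specific
#' effects start at zero, and residual variances at the per-environment pooled
#' within-cell variances.
#'
#' @param data a `met_data` object.
#' @param config a [bfa_config()].
#' @param priors a [bfa_priors()].
#' @return A `bfa_state`.
#' @export
initialize_state <- function(data, config, priors = bfa_priors()) {
  ix <- met_index(data)
  k <- config$k
  if (config$full_rank && k != ix$p) {
    stop("full-rank model requires k = p")
  }
  n_env <- ix$n_env
  if (any(n_env < 2)) {
    stop("environment(s) with fewer than 2 observations: ",
         paste(data$environments[n_env < 2], collapse = ", "),
         " (the residual-variance posterior would be degenerate)")
  }

  cnt_eb <- grouped_sum(rep(1, ix$n), ix$eb, ix$n_eb)
  beta <- grouped_sum(ix$y, ix$eb, ix$n_eb) / cnt_eb
  resid <- ix$y - beta[ix$eb]

  # pooled within-cell variance per environment
  cells_env <- tabulate(ix$eb_env, nbins = ix$p)
  s2 <- grouped_sum(resid^2, ix$e, ix$p) / pmax(n_env - cells_env, 1)
  if (any(s2 <= 0)) {
    stop("zero within-cell variance in environment(s): ",
         paste(data$environments[s2 <= 0], collapse = ", "),
         " (constant observations; nothing to fit)")
  }

  # genotype x environment table of residual means (0 where unobserved),
  # covariance across environments; cell index ge is genotype-major
  mp <- ix$m * ix$p
  sums <- grouped_sum(resid, ix$ge, mp)
  cnts <- grouped_sum(rep(1, ix$n), ix$ge, mp)
  means <- ifelse(cnts > 0, sums / pmax(cnts, 1), 0)
  Tge <- matrix(means, ix$m, ix$p, byrow = TRUE)
  S <- stats::cov(Tge)
  S[!is.finite(S)] <- 0
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lambda <- sort(sqrt(pmax(eg$values[seq_len(k)], 0)), decreasing = TRUE)
  alpha <- eg$vectors[, seq_len(k), drop = FALSE]

  # starting scores: project the two-way table onto the initial eigenvectors
  # (T alpha_k ~ lambda_k f_k under the factor structure); a zero start would
  # make the first singular-value and eigenvector conditionals degenerate
  f0 <- sweep(Tge %*% alpha, 2, pmax(lambda, 1e-8), "/")
  f0[, lambda < 1e-8] <- stats::rnorm(ix$m * sum(lambda < 1e-8))

  bfa_state(
    beta = beta, lambda = lambda, alpha = alpha,
    f = f0, delta = numeric(ix$m * ix$p),
    psi = if (config$full_rank || k == ix$p) numeric(ix$p) else rep(0.1, ix$p),
    sigma_e2 = s2
  )
}

# ---------------------------------------------------------------------------
# Full conditional samplers. Each takes the current state and returns a new
# draw of its block, leaving the rest of the state untouched. Residual
# workspaces are recomputed from the current state on every call.
# ---------------------------------------------------------------------------

#' Draw the fixed environment-block effects from their full conditional
#'
#' The conditional is Gaussian with precision `X1' R^-1 X1 + I/sigma_beta2`
#' (diagonal under cell-means coding) and mean given by the weighted cell means
#' of the partial residual that removes the genetic and specific effects.
#'
#' @param y observation vector.
#' @param state current `bfa_state`.
#' @param data a `met_data`.
#' @param priors a [bfa_priors()].
#' @return New `beta` vector.
#' @export
sample_beta <- function(y, state, data, priors = bfa_priors()) {
  ix <- met_index(data)
  G <- genetic_effects(state)
  a0 <- y - G[cbind(ix$g, ix$e)] - state$delta[ix$ge]
  w <- 1 / state$sigma_e2[ix$e]
  if (any(ix$cnt_eb == 0)) {
    stop("empty environment-block cell(s): ",
         paste(data$eb_cells$label[ix$cnt_eb == 0], collapse = ", "))
  }
  prec <- ix$cnt_eb / state$sigma_e2[ix$eb_env] + 1 / priors$sigma_beta2
  mu <- grouped_sum(w * a0, ix$eb, ix$n_eb) / prec
  stats::rnorm(ix$n_eb, mu, sqrt(1 / prec))
}

#' Draw one singular value from its truncated-normal full conditional
#'
#' The Gaussian conditional for \eqn{\lambda_k} is truncated to
#' `[lambda_{k+1}, lambda_{k-1}]` (0 below the last factor, unbounded above the
#' first) so the ordered, nonnegative constraint is preserved at every scan.
#' When the factor carries no information (its regressor is numerically zero)
#' the draw falls back to the prior restricted to the same interval, with a
#' warning.
#'
#' @param y observation vector.
#' @param state current `bfa_state`.
#' @param data a `met_data`.
#' @param k_index which singular value to update.
#' @param priors a [bfa_priors()].
#' @return New value of `lambda[k_index]`.
#' @export
sample_lambda <- function(y, state, data, k_index, priors = bfa_priors()) {
  ix <- met_index(data)
  K <- length(state$lambda)
  # partial residual removing everything except factor k_index
  lam0 <- state$lambda
  lam0[k_index] <- 0
  st0 <- state; st0$lambda <- lam0
  G <- genetic_effects(st0)
  a1 <- y - state$beta[ix$eb] - G[cbind(ix$g, ix$e)] - state$delta[ix$ge]
  a2 <- state$alpha[ix$e, k_index] * state$f[ix$g, k_index]
  w <- 1 / state$sigma_e2[ix$e]
  lower <- if (k_index < K) state$lambda[k_index + 1] else 0
  upper <- if (k_index > 1) state$lambda[k_index - 1] else Inf
  d <- sum(a2^2 * w)
  if (d < 1e-300) {
    warning("factor ", k_index,
            " carries no information; drawing its singular value from the prior")
    return(truncnorm::rtruncnorm(1, a = lower, b = upper, mean = 0,
                                 sd = sqrt(priors$lambda_prior_variance)))
  }
  prec <- d + 1 / priors$lambda_prior_variance
  mu <- sum(a2 * a1 * w) / prec
  truncnorm::rtruncnorm(1, a = lower, b = upper, mean = mu, sd = sqrt(1 / prec))
}

#' Orthonormal complement by Gram-Schmidt completion
#'
#' Given a p x s matrix with orthonormal columns, returns a p x (p - s) matrix
#' whose columns complete it to an orthonormal basis of R^p. Eigenvectors are
#' sampled in the "corrected" subspace spanned by these complement columns,
#' which removes the orthogonality constraint from the sampling step.
#'
#' @param Hs p x s matrix with orthonormal columns (s may be 0).
#' @param tol orthonormality tolerance for the input check.
#' @return p x (p - s) matrix `Hk` with `t(Hk) %*% Hs = 0` and
#'   `t(Hk) %*% Hk = I`.
#' @export
gram_schmidt_complement <- function(Hs, tol = 1e-8) {
  Hs <- as.matrix(Hs)
  p <- nrow(Hs)
  s <- ncol(Hs)
  if (s >= p) stop("cannot complement ", s, " columns in dimension ", p)
  if (s > 0) {
    G <- crossprod(Hs)
    if (max(abs(G - diag(s))) > tol) {
      stop("columns of Hs are not orthonormal")
    }
  }
  if (s == 0) return(diag(p))
  Hk <- qr.Q(qr(Hs), complete = TRUE)[, (s + 1):p, drop = FALSE]
  # one re-orthogonalization pass against Hs for numerical hygiene
  Hk <- Hk - Hs %*% crossprod(Hs, Hk)
  qr.Q(qr(Hk))
}

#' Draw one eigenvector in its Gram-Schmidt-corrected subspace
#'
#' Implements the four-step constrained update: (1) build the orthonormal
#' complement `Hk` of the eigenvectors already updated this scan; (2) draw the
#' auxiliary vector from its Gaussian conditional in the (p - s)-dimensional
#' corrected subspace; (3) normalize it (the back-transformation preserves the
#' norm); (4) map back, `alpha_k = Hk %*% alpha_tilde`. The result has unit
#' norm and is orthogonal to the eigenvectors in `Hs`. When the conditional is
#' degenerate (e.g. the factor's scores are all zero) the draw falls back to
#' the uniform distribution on the corrected-subspace sphere (the prior), with
#' a warning.
#'
#' @param y observation vector.
#' @param state current `bfa_state`.
#' @param data a `met_data`.
#' @param k_index which eigenvector to update.
#' @param Hs matrix of eigenvectors to stay orthogonal to; defaults to columns
#'   `1..(k_index - 1)` of `state$alpha`.
#' @return New unit-norm eigenvector.
#' @export
sample_alpha <- function(y, state, data, k_index,
                         Hs = state$alpha[, seq_len(k_index - 1), drop = FALSE]) {
  ix <- met_index(data)
  lam0 <- state$lambda
  lam0[k_index] <- 0
  st0 <- state; st0$lambda <- lam0
  G <- genetic_effects(st0)
  a3 <- y - state$beta[ix$eb] - G[cbind(ix$g, ix$e)] - state$delta[ix$ge]
  w <- 1 / state$sigma_e2[ix$e]
  fk <- state$f[ix$g, k_index]
  lam <- state$lambda[k_index]
  # Delta_k = lam * diag(Zf f_k) X2 has environment-indicator columns, so
  # Delta' R^-1 Delta is diagonal
  d <- lam^2 * grouped_sum(fk^2 * w, ix$e, ix$p)
  b <- lam * grouped_sum(fk * a3 * w, ix$e, ix$p)
  Hk <- gram_schmidt_complement(Hs)
  if (min(d) < 1e-300) {
    warning("degenerate eigenvector conditional for factor ", k_index,
            "; drawing uniformly on the corrected-subspace sphere")
    z <- stats::rnorm(ncol(Hk))
    return(as.vector(Hk %*% (z / sqrt(sum(z^2)))))
  }
  mu <- b / d                        # unconstrained conditional mean
  m_tilde <- crossprod(Hk, mu)
  prec <- crossprod(Hk * d, Hk)      # Hk' diag(d) Hk
  U <- chol(prec)
  a_tilde <- as.vector(m_tilde + backsolve(U, stats::rnorm(ncol(Hk))))
  a_tilde <- a_tilde / sqrt(sum(a_tilde^2))
  as.vector(Hk %*% a_tilde)
}

#' Draw the genotype factor scores from their Gaussian full conditional
#'
#' The stacked score vector (all genotypes, all factors) has precision
#' `I + A4' R^-1 A4` where `A4` collects, column-blockwise over factors, the
#' regressors `lambda_k diag(X2 alpha_k) Zf`; the identity block is the
#' standard-normal prior.
#'
#' @param y observation vector.
#' @param state current `bfa_state`.
#' @param data a `met_data`.
#' @return New m x k score matrix.
#' @export
sample_f <- function(y, state, data) {
  ix <- met_index(data)
  K <- length(state$lambda)
  a5 <- y - state$beta[ix$eb] - state$delta[ix$ge]
  sw <- sqrt(1 / state$sigma_e2[ix$e])
  A4w <- matrix(0, ix$n, ix$m * K)
  for (k in seq_len(K)) {
    A4w[cbind(seq_len(ix$n), (k - 1L) * ix$m + ix$g)] <-
      state$lambda[k] * state$alpha[ix$e, k] * sw
  }
  prec <- diag(ix$m * K) + crossprod(A4w)
  U <- chol(prec)
  mu <- backsolve(U, forwardsolve(t(U), crossprod(A4w, a5 * sw)))
  fv <- as.vector(mu) + backsolve(U, stats::rnorm(ix$m * K))
  matrix(fv, ix$m, K)
}

#' Draw the specific genetic effects from their Gaussian full conditional
#'
#' One effect per genotype x environment cell (genotype-major), with prior
#' variance given by the environment's specific variance. Cells without
#' observations are drawn from the prior. Not used in the full-rank model,
#' where the specific effects are identically zero.
#'
#' @param y observation vector.
#' @param state current `bfa_state`.
#' @param data a `met_data`.
#' @return New `delta` vector of length m * p.
#' @export
sample_delta <- function(y, state, data) {
  ix <- met_index(data)
  if (any(state$psi <= 0)) {
    stop("specific variance is zero: the specific-effect prior is degenerate ",
         "(use the full-rank model to drop the specific effects)")
  }
  G <- genetic_effects(state)
  a7 <- y - state$beta[ix$eb] - G[cbind(ix$g, ix$e)]
  w <- 1 / state$sigma_e2[ix$e]
  mp <- ix$m * ix$p
  prec <- ix$cnt_ge / state$sigma_e2[ix$cell_env] + 1 / state$psi[ix$cell_env]
  mu <- grouped_sum(w * a7, ix$ge, mp) / prec
  stats::rnorm(mp, mu, sqrt(1 / prec))
}

#' Draw the specific variances from their scaled inverse chi-squared conditional
#'
#' For environment k the update is
#' `Scale-inv-chi2(m + nu_k, (delta_k' delta_k + nu_k S_k2) / (m + nu_k))`,
#' where `delta_k` collects the m specific effects of that environment.
#'
#' @param state current `bfa_state`.
#' @param data a `met_data`.
#' @param priors a [bfa_priors()].
#' @return New `psi` vector (one variance per environment).
#' @export
sample_psi <- function(state, data, priors = bfa_priors()) {
  ix <- met_index(data)
  ss <- grouped_sum(state$delta^2, ix$cell_env, ix$p)
  df <- ix$m + priors$nu_k
  scale <- (ss + priors$nu_k * priors$S_k2) / df
  rscinvchisq(ix$p, df, scale)
}

#' Draw the residual variances from their scaled inverse chi-squared conditional
#'
#' For environment k the update is
#' `Scale-inv-chi2(n_k + nu_e, (SSR_k + nu_e S_e2) / (n_k + nu_e))` with
#' `SSR_k` the residual sum of squares of that environment's observations about
#' the current fitted mean.
#'
#' @param y observation vector.
#' @param state current `bfa_state`.
#' @param data a `met_data`.
#' @param priors a [bfa_priors()].
#' @return New `sigma_e2` vector.
#' @export
sample_sigma_e <- function(y, state, data, priors = bfa_priors()) {
  ix <- met_index(data)
  G <- genetic_effects(state)
  theta <- state$beta[ix$eb] + G[cbind(ix$g, ix$e)] + state$delta[ix$ge]
  n_env <- ix$n_env
  if (any(n_env == 0)) stop("environment without observations")
  ssr <- grouped_sum((y - theta)^2, ix$e, ix$p)
  df <- n_env + priors$nu_e
  scale <- (ssr + priors$nu_e * priors$S_e2) / df
  rscinvchisq(ix$p, df, scale)
}

# ---------------------------------------------------------------------------
# the Gibbs driver
# ---------------------------------------------------------------------------

#' Fit the Bayesian factor analytic model by Gibbs sampling
#'
#' Runs the Gibbs sampler over the closed-form full conditionals in the scan
#' order beta, lambda_1..k, alpha_1..k, f, delta, psi, sigma_e2, recomputing
#' the partial residuals from the current state before each conditional.
#' Eigenvectors are drawn in the Gram-Schmidt-corrected subspace so every scan
#' satisfies the orthonormality and ordering constraints; violations at any
#' retained draw are a hard failure. Retained draws are sign-aligned (each
#' eigenvector's dominant coordinate made positive, flipping the matching
#' scores jointly) so posterior summaries are not corrupted by the sign
#' invariance of the likelihood; the alignment is a summary-time relabeling
#' that does not alter the chain's law.
#'
#' @param data a `met_data` object.
#' @param config a [bfa_config()].
#' @param priors a [bfa_priors()].
#' @param verbose print progress every 1000 scans?
#' @return An object of class `bfa_chain`: retained draws of every parameter
#'   (`beta`, `lambda`, `alpha`, `f`, `delta`, `psi`, `sigma_e2`), the
#'   per-draw log-likelihood, and the configuration, priors, seed and data
#'   descriptors used.
#' @export
run_gibbs <- function(data, config, priors = bfa_priors(), verbose = FALSE) {
  stopifnot(inherits(data, "met_data"), inherits(config, "bfa_config"))
  set.seed(config$seed)
  full_rank <- config$full_rank || config$k == data$p
  if (config$k > data$p) stop("k cannot exceed the number of environments")
  st <- initialize_state(data, config, priors)
  ix <- met_index(data)
  y <- ix$y
  K <- config$k
  R_keep <- n_retained(config$iterations, config$burn_in, config$thin)
  if (R_keep < 1) stop("chain settings retain no draws")

  draws <- list(
    beta = matrix(NA_real_, R_keep, ix$n_eb,
                  dimnames = list(NULL, data$eb_cells$label)),
    lambda = matrix(NA_real_, R_keep, K),
    alpha = array(NA_real_, c(R_keep, ix$p, K),
                  dimnames = list(NULL, data$environments, NULL)),
    f = array(NA_real_, c(R_keep, ix$m, K),
              dimnames = list(NULL, data$genotypes, NULL)),
    delta = matrix(NA_real_, R_keep, ix$m * ix$p),
    psi = matrix(NA_real_, R_keep, ix$p, dimnames = list(NULL, data$environments)),
    sigma_e2 = matrix(NA_real_, R_keep, ix$p,
                      dimnames = list(NULL, data$environments)),
    loglik = numeric(R_keep)
  )

  amean <- matrix(0, ix$p, K)   # running mean of sign-aligned eigenvectors
  kept <- 0L
  for (it in seq_len(config$iterations)) {
    st$beta <- sample_beta(y, st, data, priors)
    for (k in seq_len(K)) st$lambda[k] <- sample_lambda(y, st, data, k, priors)
    for (k in seq_len(K)) st$alpha[, k] <- sample_alpha(y, st, data, k)
    st$f <- sample_f(y, st, data)
    if (!full_rank) {
      st$delta <- sample_delta(y, st, data)
      st$psi <- sample_psi(st, data, priors)
    }
    st$sigma_e2 <- sample_sigma_e(y, st, data, priors)

    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0 &&
        kept < R_keep) {
      ok <- tryCatch({ validate_state(st); TRUE },
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) stop("model-state invariant violated at scan ", it, ": ", ok)
      kept <- kept + 1L

      a <- st$alpha
      f <- st$f
      ref <- if (kept == 1L) a else amean
      for (k in seq_len(K)) {
        j <- which.max(abs(ref[, k]))
        if (a[j, k] < 0) {
          a[, k] <- -a[, k]
          f[, k] <- -f[, k]
        }
      }
      amean <- amean * ((kept - 1) / kept) + a / kept

      draws$beta[kept, ] <- st$beta
      draws$lambda[kept, ] <- st$lambda
      draws$alpha[kept, , ] <- a
      draws$f[kept, , ] <- f
      draws$delta[kept, ] <- st$delta
      draws$psi[kept, ] <- st$psi
      draws$sigma_e2[kept, ] <- st$sigma_e2
      G <- genetic_effects(st)
      theta <- st$beta[ix$eb] + G[cbind(ix$g, ix$e)] + st$delta[ix$ge]
      draws$loglik[kept] <- loglik_idx(y, theta, ix$e, st$sigma_e2, ix$n)
    }
    if (verbose && it %% 1000 == 0) {
      message("scan ", it, "/", config$iterations)
    }
  }

  structure(
    c(draws,
      list(config = config, priors = priors, seed = config$seed,
           full_rank = full_rank, retained = R_keep,
           m = data$m, p = data$p, q = data$q, n = data$n,
           genotypes = data$genotypes, environments = data$environments,
           eb_cells = data$eb_cells)),
    class = "bfa_chain"
  )
}

#' Fit a Bayesian factor analytic model (convenience wrapper)
#'
#' Thin wrapper around [bfa_config()] + [run_gibbs()].
#'
#' @param data a `met_data` object.
#' @param k number of common factors; defaults to the full-rank model (k = p).
#' @param iterations,burn_in,thin,seed chain controls.
#' @param priors a [bfa_priors()].
#' @param ... passed to [run_gibbs()].
#' @return A `bfa_chain`.
#' @export
bfa_fit <- function(data, k = data$p, iterations = 6000, burn_in = 1000,
                    thin = 2, seed = 1, priors = bfa_priors(), ...) {
  cfg <- bfa_config(k = k, iterations = iterations, burn_in = burn_in,
                    thin = thin, seed = seed, full_rank = (k == data$p))
  run_gibbs(data, cfg, priors, ...)
}

#' @export
print.bfa_chain <- function(x, ...) {
  cat("BFA chain: ", x$retained, " retained draws (iterations = ",
      x$config$iterations, ", burn-in = ", x$config$burn_in, ", thin = ",
      x$config$thin, ", seed = ", x$seed, ")\n", sep = "")
  cat("model: k = ", x$config$k, if (x$full_rank) " (full rank)",
      ", m = ", x$m, " genotypes, p = ", x$p, " environments, n = ", x$n,
      " records\n", sep = "")
  invisible(x)
}
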