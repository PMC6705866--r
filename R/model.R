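#' Create a model state for the Bayesian factor analytic model
#'
#' One complete configuration of the model unknowns: fixed environment-block
#' effects `beta`, ordered nonnegative singular values `lambda`, orthonormal
#' eigenvector columns `alpha` (p x k), genotype factor scores `f` (m x k),
#' specific genetic effects `delta` (one per genotype x environment cell,
#' genotype-major), specific variances `psi` (per environment) and residual
#' variances `sigma_e2` (per environment). In the full-rank model (k = p) the
#' specific effects and variances are identically zero.
#'
#' @param beta,lambda,alpha,f,delta,psi,sigma_e2 components as described above.
#' @param check validate the invariants (ordering, orthonormality, variance
#'   positivity)? Default `TRUE`.
#' @return An object of class `bfa_state`.
#' @export
bfa_state <- function(beta, lambda, alpha, f, delta, psi, sigma_e2,
                      check = TRUE) {
  alpha <- as.matrix(alpha)
  f <- as.matrix(f)
  st <- structure(list(beta = as.numeric(beta), lambda = as.numeric(lambda),
                       alpha = alpha, f = f, delta = as.numeric(delta),
                       psi = as.numeric(psi), sigma_e2 = as.numeric(sigma_e2)),
                  class = "bfa_state")
  if (check) validate_state(st)
  st
}

#' Validate the invariants of a model state
#'
#' Checks the ordering of the singular values, orthonormality of the
#' eigenvector columns, nonnegativity of the specific variances, positivity of
#' the residual variances, and (when k = p) nullity of the specific variances.
#'
#' @param state a `bfa_state`.
#' @param tol orthonormality tolerance.
#' @return `state`, invisibly; errors on violation.
#' @export
validate_state <- function(state, tol = 1e-8) {
  k <- length(state$lambda)
  p <- nrow(state$alpha)
  if (ncol(state$alpha) != k || ncol(state$f) != k) {
    stop("alpha/f column count does not match the number of factors")
  }
  if (length(state$delta) != nrow(state$f) * p) {
    stop("delta must have one entry per genotype x environment cell")
  }
  if (length(state$psi) != p || length(state$sigma_e2) != p) {
    stop("psi and sigma_e2 must have one entry per environment")
  }
  if (any(state$lambda < -tol) || any(diff(state$lambda) > tol)) {
    stop("singular values must satisfy lambda_1 >= ... >= lambda_k >= 0")
  }
  if (k > 0) {
    G <- crossprod(state$alpha)
    if (max(abs(G - diag(k))) > tol) {
      stop("eigenvector columns are not orthonormal (max deviation ",
           format(max(abs(G - diag(k)))), ")")
    }
  }
  if (any(state$psi < 0)) stop("specific variances must be nonnegative")
  if (any(state$sigma_e2 <= 0)) stop("residual variances must be positive")
  if (k == p && any(state$psi != 0)) {
    stop("full-rank model (k = p) requires psi == 0")
  }
  invisible(state)
}

# m x p matrix of common-factor genetic effects: sum_k lambda_k f_{.k} alpha_k'
genetic_effects <- function(state) {
  if (length(state$lambda) == 0) {
    return(matrix(0, nrow(state$f), nrow(state$alpha)))
  }
  state$f %*% (state$lambda * t(state$alpha))
}

#' Fitted mean of the factor analytic model
#'
#' Evaluates the summation form of the model mean,
#' \deqn{\theta = X_1\beta + \sum_k \lambda_k\,\mathrm{diag}(X_2\alpha_k)\,Z_f f_k + Z\delta,}
#' one value per observation.
#'
#' @param state a `bfa_state`.
#' @param dm design matrices from [build_design_matrices()].
#' @return Numeric n-vector.
#' @export
predict_mean <- function(state, dm) {
  stopifnot(inherits(dm, "met_design"))
  p <- ncol(dm$X2); m <- ncol(dm$Zf); k <- length(state$lambda)
  if (length(state$beta) != ncol(dm$X1) || nrow(state$alpha) != p ||
      nrow(state$f) != m || length(state$delta) != ncol(dm$Z)) {
    stop("state dimensions do not conform to the design matrices")
  }
  theta <- as.vector(dm$X1 %*% state$beta) + as.vector(dm$Z %*% state$delta)
  for (j in seq_len(k)) {
    theta <- theta + state$lambda[j] *
      as.vector(dm$X2 %*% state$alpha[, j]) * as.vector(dm$Zf %*% state$f[, j])
  }
  theta
}

#' Log-likelihood of the factor analytic model
#'
#' Gaussian log-density of the observations with mean [predict_mean()] and
#' block-diagonal residual covariance (homogeneous within an environment,
#' heterogeneous across environments).
#'
#' @param state a `bfa_state`.
#' @param data a `met_data` object.
#' @param dm design matrices; built from `data` when omitted.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(state, data, dm = build_design_matrices(data)) {
  if (any(state$sigma_e2 <= 0)) stop("residual variances must be positive")
  theta <- predict_mean(state, dm)
  r <- data$records$value - theta
  s2 <- state$sigma_e2[data$records$env_id]
  -0.5 * (data$n * log(2 * pi) + sum(log(s2)) + sum(r^2 / s2))
}

# log-likelihood from precomputed index vectors (sampler hot path)
loglik_idx <- function(y, theta, env_id, sigma_e2, n) {
  s2 <- sigma_e2[env_id]
  -0.5 * (n * log(2 * pi) + sum(log(s2)) + sum((y - theta)^2 / s2))
}

#' Genetic covariance implied by a model state
#'
#' Reconstructs the genetic covariance across environments from the spectral
#' parameterization, \eqn{\Sigma = \sum_k \lambda_k^2 \alpha_k\alpha_k' + \Psi}.
#' It is symmetric positive semidefinite by construction (no Heywood cases).
#'
#' @param state a `bfa_state`.
#' @return p x p covariance matrix.
#' @export
implied_genetic_covariance <- function(state) {
  p <- nrow(state$alpha)
  S <- diag(state$psi, p, p)
  for (j in seq_along(state$lambda)) {
    S <- S + state$lambda[j]^2 * tcrossprod(state$alpha[, j])
  }
  (S + t(S)) / 2
}
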