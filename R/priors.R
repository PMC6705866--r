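#' Prior specification for the Bayesian factor analytic model
#'
#' The priors follow the classical factor-model assumptions: an (effectively
#' flat) Gaussian prior on the fixed environment-block effects, a positive
#' Gaussian prior on the singular values truncated to the ordered region
#' \eqn{\lambda_1 \ge \dots \ge \lambda_k \ge 0}, a uniform spherical prior on
#' each eigenvector in its corrected subspace, standard-normal factor scores,
#' Gaussian specific effects with per-environment specific variances
#' \eqn{\psi_k}, and scaled inverse chi-squared priors on the specific and
#' residual variances.
#'
#' @param sigma_beta2 prior variance of the fixed effects (trait units squared);
#'   the default 1e12 makes the prior effectively flat.
#' @param nu_e,S_e2 degrees of freedom and scale of the scaled inverse
#'   chi-squared prior on each per-environment residual variance. The default
#'   (0, 0) is the scale-invariant limit \eqn{1/\sigma^2}.
#' @param nu_k,S_k2 degrees of freedom and scale for the specific variances.
#'   The default is (1, 0), the value the specific-variance conditional update
#'   operates with.
#' @param lambda_prior_variance prior variance of each singular value before
#'   truncation; the default 1e12 is effectively flat on the ordered cone.
#' @return An object of class `bfa_priors` (a named list).
#' @export
bfa_priors <- function(sigma_beta2 = 1e12, nu_e = 0, S_e2 = 0,
                       nu_k = 1, S_k2 = 0, lambda_prior_variance = 1e12) {
  stopifnot(sigma_beta2 > 0, nu_e >= 0, S_e2 >= 0, nu_k >= 0, S_k2 >= 0,
            lambda_prior_variance > 0)
  structure(list(sigma_beta2 = sigma_beta2, nu_e = nu_e, S_e2 = S_e2,
                 nu_k = nu_k, S_k2 = S_k2,
                 lambda_prior_variance = lambda_prior_variance),
            class = "bfa_priors")
}

#' @export
print.bfa_priors <- function(x, ...) {
  cat("BFA priors:\n",
      "  fixed effects        N(0, ", format(x$sigma_beta2), ")\n",
      "  singular values      N+(0, ", format(x$lambda_prior_variance),
      ") on the ordered cone\n",
      "  residual variances   Scale-inv-chi2(", x$nu_e, ", ", x$S_e2, ")\n",
      "  specific variances   Scale-inv-chi2(", x$nu_k, ", ", x$S_k2, ")\n",
      sep = "")
  invisible(x)
}

# Scaled inverse chi-squared draws: df * scale / chi2_df.
rscinvchisq <- function(n, df, scale) {
  df * scale / stats::rchisq(n, df)
}
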