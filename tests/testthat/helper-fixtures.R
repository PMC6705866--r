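# Fixtures shared across test files; everything is built in code.

# complete m x p x q layout with values from a supplied function or vector
toy_met_df <- function(m = 3, p = 2, q = 2, values = NULL) {
  df <- expand.grid(block = paste0("B", seq_len(q)),
                    env = paste0("E", seq_len(p)),
                    gen = paste0("G", seq_len(m)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("gen", "env", "block")]
  df$y <- if (is.null(values)) seq_len(nrow(df)) else values
  df
}

# random small model state conforming to (m, p, k)
random_state <- function(m, p, k, n_eb, seed = 1) {
  set.seed(seed)
  alpha <- qr.Q(qr(matrix(rnorm(p * p), p, p)))[, seq_len(k), drop = FALSE]
  bfa_state(
    beta = rnorm(n_eb),
    lambda = sort(abs(rnorm(k, sd = 2)), decreasing = TRUE),
    alpha = alpha,
    f = matrix(rnorm(m * k), m, k),
    delta = rnorm(m * p, sd = 0.3),
    psi = if (k == p) numeric(p) else runif(p, 0.2, 1),
    sigma_e2 = runif(p, 0.5, 2)
  )
}

# a small unbalanced dataset: complete layout minus a couple of cells
unbalanced_met <- function(seed = 42) {
  df <- toy_met_df(m = 6, p = 3, q = 2)
  set.seed(seed)
  df$y <- rnorm(nrow(df), mean = 10)
  drop <- with(df, (gen == "G2" & env == "E3") | (gen == "G5" & env == "E1"))
  met_data(df[!drop, ])
}

# dense-matrix Gaussian conditional moments: mean and covariance of
# N((A'WA + P)^-1 A'W b, (A'WA + P)^-1) with W = diag(w)
dense_gaussian_moments <- function(A, b, w, prior_prec) {
  prec <- crossprod(A, A * w) + prior_prec
  V <- solve(prec)
  list(mean = as.vector(V %*% crossprod(A, b * w)), cov = V)
}

expect_moments_match <- function(draws, mean_true, var_true, n_sigma = 4) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  emp_mean <- colMeans(draws)
  se_mean <- sqrt(var_true / n)
  expect_true(all(abs(emp_mean - mean_true) < n_sigma * se_mean),
              label = paste("empirical means within", n_sigma, "MC standard errors"))
  emp_var <- apply(draws, 2, var)
  se_var <- var_true * sqrt(2 / (n - 1))
  expect_true(all(abs(emp_var - var_true) < n_sigma * se_var),
              label = paste("empirical variances within", n_sigma, "MC standard errors"))
}
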