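# Monte-Carlo checks of every full conditional against dense closed-form
# moments or analytic CDFs, on a fixed 3-genotype x 2-environment instance.

cond_fixture <- function(seed = 11) {
  set.seed(seed)
  df <- toy_met_df(m = 3, p = 2, q = 2)
  df$y <- rnorm(12, mean = 5, sd = 1.5)
  md <- met_data(df)
  dm <- build_design_matrices(md)
  st <- random_state(3, 2, 2, nrow(md$eb_cells), seed = seed + 1)
  st$psi <- c(0.7, 1.3)   # k < p would be full rank here; force a proper prior
  list(md = md, dm = dm, st = st, y = md$records$value)
}

test_that("fixed-effect conditional matches its closed-form Gaussian", {
  fx <- cond_fixture()
  st <- fx$st
  G <- fx$st$f %*% (st$lambda * t(st$alpha))
  a0 <- fx$y - G[cbind(fx$md$records$gen_id, fx$md$records$env_id)] -
    st$delta[fx$md$records$ge]
  w <- 1 / st$sigma_e2[fx$md$records$env_id]
  mom <- dense_gaussian_moments(fx$dm$X1, a0, w, diag(1e-12, 4))

  set.seed(99)
  draws <- t(replicate(2e4, sample_beta(fx$y, st, fx$md)))
  expect_moments_match(draws, mom$mean, diag(mom$cov))

  # identity-design sanity: one record per cell, unit variances, no genetic
  # effects -> conditional is N(y, I)
  md1 <- met_data(data.frame(gen = rep("G1", 3), env = c("E1", "E2", "E3"),
                             block = "B1", y = c(1, -2, 0.5)))
  st1 <- bfa_state(beta = numeric(3), lambda = 1, alpha = matrix(c(1, 0, 0)),
                   f = matrix(0, 1, 1), delta = numeric(3),
                   psi = rep(1, 3), sigma_e2 = rep(1, 3))
  set.seed(1)
  d1 <- t(replicate(2e4, sample_beta(c(1, -2, 0.5), st1, md1)))
  expect_moments_match(d1, c(1, -2, 0.5), rep(1, 3))
})

test_that("singular-value conditional is the stated truncated normal", {
  # craft the data so the conditional mean sits close to the active lower
  # bound: y carries the factor-1 signal at strength ~ lambda_2
  fx <- cond_fixture()
  st <- fx$st
  st$beta[] <- 0
  st$delta[] <- 0
  st$lambda <- c(2, 1e-6)
  r <- fx$md$records
  a2 <- st$alpha[r$env_id, 1] * st$f[r$gen_id, 1]
  set.seed(12)
  y <- 1.1 * a2 + rnorm(12, 0, 0.6)
  md <- fx$md
  md$records$value <- y
  md$idx$y <- y

  w <- 1 / st$sigma_e2[r$env_id]
  prec <- sum(a2^2 * w) + 1e-12
  mu <- sum(a2 * y * w) / prec
  sd_ <- sqrt(1 / prec)
  lower <- st$lambda[2]

  set.seed(7)
  draws <- replicate(5e4, sample_lambda(y, st, md, 1))
  expect_true(all(draws >= lower))

  # rejection-sampling oracle of the same truncated normal
  set.seed(8)
  orc <- rnorm(3e5, mu, sd_)
  orc <- orc[orc >= lower]
  expect_gte(length(orc), 5e4)
  orc <- orc[seq_len(5e4)]
  ks <- suppressWarnings(ks.test(draws, orc))
  expect_gt(ks$p.value, 0.01)

  # a mean far below an active bound still respects the bound (second factor,
  # bounded above by the first and below by zero)
  set.seed(9)
  d2 <- replicate(2e3, sample_lambda(y, st, md, 2))
  expect_true(all(d2 >= 0 & d2 <= st$lambda[1]))
})

test_that("truncation bounds are respected and inactive bounds are harmless", {
  # far-inside mean: draws indistinguishable from the untruncated normal
  set.seed(2)
  x <- truncnorm::rtruncnorm(1e5, a = -50, b = 50, mean = 0.3, sd = 1)
  ks <- suppressWarnings(ks.test(x, "pnorm", 0.3, 1))
  expect_gt(ks$p.value, 0.01)
  # mean far below an active lower bound
  y <- truncnorm::rtruncnorm(1e5, a = 0, b = Inf, mean = -10, sd = 1)
  expect_true(all(y >= 0))
})

test_that("factor-score conditional matches a dense closed-form oracle", {
  fx <- cond_fixture()
  st <- fx$st
  r <- fx$md$records
  w <- 1 / st$sigma_e2[r$env_id]
  a5 <- fx$y - st$beta[r$eb] - st$delta[r$ge]
  A4 <- matrix(0, 12, 6)
  for (k in 1:2) {
    A4[cbind(1:12, (k - 1) * 3 + r$gen_id)] <-
      st$lambda[k] * st$alpha[r$env_id, k]
  }
  mom <- dense_gaussian_moments(A4, a5, w, diag(6))

  set.seed(21)
  draws <- t(replicate(2e4, as.vector(sample_f(fx$y, st, fx$md))))
  expect_moments_match(draws, mom$mean, diag(mom$cov))
})

test_that("single-genotype single-factor score conditional is the unit ridge", {
  # one observation, lambda = 1, alpha = e1, R = I: posterior N(a5/2, 1/2)
  md <- met_data(data.frame(gen = "G1", env = "E1", block = "B1", y = 3))
  st <- bfa_state(beta = 0, lambda = 1, alpha = matrix(1, 1, 1),
                  f = matrix(0, 1, 1), delta = 0, psi = numeric(1),
                  sigma_e2 = 1)
  set.seed(3)
  draws <- replicate(2e4, sample_f(3, st, md)[1, 1])
  expect_moments_match(matrix(draws), 3 / 2, 1 / 2)
})

test_that("specific-effect conditional matches dense and scalar oracles", {
  fx <- cond_fixture()
  st <- fx$st
  r <- fx$md$records
  w <- 1 / st$sigma_e2[r$env_id]
  G <- st$f %*% (st$lambda * t(st$alpha))
  a7 <- fx$y - st$beta[r$eb] - G[cbind(r$gen_id, r$env_id)]
  Z <- fx$dm$Z
  Minv <- diag(1 / rep(st$psi, 3))
  mom <- dense_gaussian_moments(Z, a7, w, Minv)

  set.seed(31)
  draws <- t(replicate(2e4, sample_delta(fx$y, st, fx$md)))
  expect_moments_match(draws, mom$mean, diag(mom$cov))

  # scalar conjugacy: one cell, two replicates, R = I, psi = 1 ->
  # N(2 rbar / 3, 1/3)
  md1 <- met_data(data.frame(gen = "G1", env = "E1", block = c("B1", "B2"),
                             y = c(1, 2)))
  st1 <- bfa_state(beta = c(0, 0), lambda = numeric(0),
                   alpha = matrix(numeric(0), 1, 0),
                   f = matrix(numeric(0), 1, 0), delta = 0, psi = 1,
                   sigma_e2 = 1, check = FALSE)
  set.seed(4)
  d1 <- replicate(2e4, sample_delta(c(1, 2), st1, md1))
  expect_moments_match(matrix(d1), 2 * 1.5 / 3, 1 / 3)

  st_bad <- fx$st
  st_bad$psi <- c(0, 1)
  expect_error(sample_delta(fx$y, st_bad, fx$md), "degenerate")
})

test_that("psi shrinks the specific effects to zero in the tight-prior limit", {
  fx <- cond_fixture()
  st <- fx$st
  st$psi <- rep(1e-12, 2)
  set.seed(5)
  draws <- t(replicate(200, sample_delta(fx$y, st, fx$md)))
  expect_lt(max(abs(colMeans(draws))), 1e-5)
})

test_that("specific-variance conditional is the stated scaled inverse chi-squared", {
  # nu_k = 1, S2 = 0, delta all ones over 4 genotypes in 1 environment:
  # Scale-inv-chi2(5, 4/5) with mean df*scale/(df-2) = 4/3
  md <- met_data(data.frame(gen = paste0("G", 1:4), env = "E1",
                            block = "B1", y = rnorm(4)))
  st <- bfa_state(beta = numeric(1), lambda = numeric(0),
                  alpha = matrix(numeric(0), 1, 0),
                  f = matrix(numeric(0), 4, 0), delta = rep(1, 4), psi = 1,
                  sigma_e2 = 1, check = FALSE)
  set.seed(6)
  draws <- replicate(5e4, sample_psi(st, md))
  mean_true <- 5 * (4 / 5) / 3
  var_true <- 2 * 5^2 * (4 / 5)^2 / (3^2 * 1)  # 2 df^2 s^4 /((df-2)^2 (df-4))
  expect_lt(abs(mean(draws) - mean_true), 4 * sqrt(var_true / 5e4))

  # analytic-CDF oracle: P(X <= x) = P(chi2_df >= df*scale/x)
  ks <- suppressWarnings(ks.test(draws, function(x)
    pchisq(5 * (4 / 5) / x, df = 5, lower.tail = FALSE)))
  expect_gt(ks$p.value, 0.01)

  # zero specific effects degenerate at 0
  st0 <- st; st0$delta <- rep(0, 4)
  expect_equal(max(replicate(100, sample_psi(st0, md))), 0)
})

test_that("residual-variance conditional is the stated scaled inverse chi-squared", {
  # n_k = 4, residuals all 1: Scale-inv-chi2(4, 1), mean 4/2 = 2
  md <- met_data(data.frame(gen = paste0("G", 1:4), env = "E1",
                            block = "B1", y = rep(1, 4)))
  st <- bfa_state(beta = numeric(1), lambda = numeric(0),
                  alpha = matrix(numeric(0), 1, 0),
                  f = matrix(numeric(0), 4, 0), delta = rep(0, 4), psi = 1,
                  sigma_e2 = 1, check = FALSE)
  st$beta <- 0   # residuals are exactly y = 1
  set.seed(61)
  draws <- replicate(5e4, sample_sigma_e(rep(1, 4), st, md))
  expect_lt(abs(mean(draws) - 2), 4 * sqrt(var(draws) / 5e4))
  ks <- suppressWarnings(ks.test(draws, function(x)
    pchisq(4 / x, df = 4, lower.tail = FALSE)))
  expect_gt(ks$p.value, 0.01)

  # zero residuals concentrate at 0
  st0 <- st
  expect_equal(max(replicate(100, sample_sigma_e(rep(0, 4), st0, md))), 0)
})
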