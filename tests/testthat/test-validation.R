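test_that("fold plans partition the cells with near-equal sizes under the constraints", {
  sim <- simulate_met(seed = 1)   # 20 x 5 complete: 100 observed cells
  for (nf in c(10, 3, 2)) {
    plan <- make_cell_folds(sim$data, nf, seed = 3)
    sizes <- vapply(plan$folds, nrow, integer(1))
    expect_equal(sum(sizes), 100)
    expect_lte(max(sizes) - min(sizes), 1)
    # union of folds = all observed cells, no overlap
    all_cells <- do.call(rbind, plan$folds)[, c("gen_id", "env_id")]
    expect_equal(nrow(unique(all_cells)), 100)
    # every training set keeps every genotype and environment
    for (fd in plan$folds) {
      kept <- sim$data$cell_table > 0
      kept[cbind(fd$gen_id, fd$env_id)] <- FALSE
      expect_true(all(rowSums(kept) >= 1))
      expect_true(all(colSums(kept) >= 1))
    }
  }
  # 10-fold deletes 10% of cells per fold, 3-fold ~33%, 2-fold 50%
  expect_equal(nrow(make_cell_folds(sim$data, 10, seed = 1)$folds[[1]]), 10)
  expect_equal(nrow(make_cell_folds(sim$data, 2, seed = 1)$folds[[1]]), 50)
})

test_that("fold plans are reproducible under the seed", {
  sim <- simulate_met(seed = 2)
  p1 <- make_cell_folds(sim$data, 3, seed = 11)
  p2 <- make_cell_folds(sim$data, 3, seed = 11)
  expect_identical(p1$folds, p2$folds)
})

test_that("a genotype observed in a single cell is never orphaned", {
  df <- toy_met_df(m = 4, p = 3, q = 1)
  set.seed(4)
  df$y <- rnorm(nrow(df))
  # G1 exists only in E1
  df <- df[!(df$gen == "G1" & df$env != "E1"), ]
  md <- met_data(df)
  plan <- tryCatch(make_cell_folds(md, 2, seed = 5, max_tries = 200),
                   error = function(e) e)
  if (inherits(plan, "error")) {
    expect_match(conditionMessage(plan), "G1")
  } else {
    for (fd in plan$folds) {
      expect_false(any(fd$gen == "G1" & fd$env == "E1"))
    }
  }
})

test_that("PRESS, correlation, SE and AICM match hand arithmetic and loop oracles", {
  expect_equal(press(c(1, 2), c(1, 2)), 0)
  expect_equal(press(c(0, 2), c(1, 0)), 2.5)
  set.seed(5)
  y <- rnorm(40); yh <- rnorm(40)
  loop <- 0
  for (i in seq_along(y)) loop <- loop + (y[i] - yh[i])^2
  expect_equal(press(y, yh), loop / 40)
  expect_error(press(1:3, 1:4), "mismatch")

  expect_equal(prediction_correlation(y, y), 1)
  yc <- y - mean(y)
  expect_equal(prediction_correlation(yc, -yc), -1)
  num <- sum((y - mean(y)) * (yh - mean(yh)))
  den <- sqrt(sum((y - mean(y))^2) * sum((yh - mean(yh))^2))
  expect_equal(prediction_correlation(y, yh), num / den)
  expect_error(prediction_correlation(rep(1, 5), 1:5), "zero variance")

  expect_equal(statistical_efficiency(2, 2), 1)
  expect_equal(statistical_efficiency(2, 4), 0.5)
  expect_error(statistical_efficiency(1, 0), "positive")

  expect_equal(aicm(c(-2, -2)), -4)       # zero variance: 2 * mean
  expect_equal(aicm(c(-1, -3)), -8)       # mean -2, var 2 -> 2(-2 - 2)
  ll <- rnorm(100, -50, 3)
  expect_equal(aicm(ll), 2 * (mean(ll) - var(ll)))
  expect_error(aicm(-1), "at least 2")
})

test_that("deleted-cell predictions reduce to closed forms for degenerate chains", {
  sim <- simulate_met(simulation_design(m = 5, p = 3, q = 2, groups = c(1, 1, 3),
                                        sigma_e2 = c(0.5, 1, 2)), seed = 6)
  md <- sim$data
  # chain concentrated at a known state (all genetic parameters zero ->
  # prediction is the environment's fixed-effect average)
  st <- initialize_state(md, bfa_config(k = 3, iterations = 10, seed = 1,
                                        full_rank = TRUE))
  st$lambda <- c(3e-9, 2e-9, 1e-9)
  st$f[] <- 0
  R <- 150
  ch <- list(beta = matrix(st$beta, R, length(st$beta), byrow = TRUE),
             lambda = matrix(st$lambda, R, 3, byrow = TRUE),
             alpha = aperm(array(st$alpha, c(3, 3, R)), c(3, 1, 2)),
             f = aperm(array(st$f, c(5, 3, R)), c(3, 1, 2)),
             delta = matrix(0, R, 15),
             psi = matrix(0, R, 3), sigma_e2 = matrix(1, R, 3),
             loglik = rep(-1, R), config = bfa_config(k = 3, iterations = R),
             retained = R, full_rank = TRUE, m = 5, p = 3, n = 30,
             genotypes = md$genotypes, environments = md$environments,
             eb_cells = md$eb_cells)
  class(ch) <- "bfa_chain"
  cells <- data.frame(gen = c("G1", "G4"), env = c("E2", "E3"))
  pred <- predict_deleted_cells(ch, cells)
  env_means <- as.numeric(tapply(st$beta, md$eb_cells$env_id, mean))
  expect_equal(pred, unname(env_means[c(2, 3)]))

  # with a nonzero known state the prediction equals the state's cell mean
  st2 <- st
  st2$lambda <- c(2, 1, 0.5)
  set.seed(8)
  st2$f <- matrix(rnorm(15), 5, 3)
  ch$lambda <- matrix(st2$lambda, R, 3, byrow = TRUE)
  ch$f <- aperm(array(st2$f, c(5, 3, R)), c(3, 1, 2))
  pred2 <- predict_deleted_cells(ch, cells)
  G <- genetic <- st2$f %*% (st2$lambda * t(st2$alpha))
  expect_equal(pred2, unname(env_means[c(2, 3)]) + G[cbind(c(1, 4), c(2, 3))])

  expect_error(predict_deleted_cells(ch, data.frame(gen = "G99", env = "E1")),
               "absent")
})

test_that("cross-validation on a small trial returns coherent fold metrics", {
  sim <- simulate_met(simulation_design(m = 10, p = 3, q = 2,
                                        groups = c(3, 3, 4),
                                        sigma_e2 = c(0.5, 1, 1.5)), seed = 9)
  cv <- run_cv(sim$data, folds = 3, iterations = 800, burn_in = 200, thin = 2,
               seed = 12)
  expect_s3_class(cv, "bfa_cv")
  expect_equal(nrow(cv$per_fold), 3)
  expect_equal(sum(cv$per_fold$n_cells), 30)
  expect_true(all(cv$per_fold$press >= 0))
  expect_true(all(abs(cv$per_fold$correlation) <= 1))
  # pooled PRESS equals PRESS of the pooled residuals
  expect_equal(cv$press, press(cv$predictions$observed, cv$predictions$predicted))
})

test_that("order selection reports SE = 1 for the full model and ranks coherently", {
  sim <- simulate_met(simulation_design(m = 10, p = 3, q = 2,
                                        groups = c(3, 3, 4),
                                        sigma_e2 = c(0.5, 1, 1.5)), seed = 10)
  tab <- select_k(sim$data, orders = c(1, 3), n_folds = 3, seed = 13,
                  iterations = 800, burn_in = 200, thin = 2)
  expect_equal(tab$k, c(1, 3))
  expect_equal(tab$se[tab$k == 3], 1)
  expect_equal(tab$delta_aicm[tab$k == 3], 0)
  expect_true(all(sort(tab$rank_press) == c(1, 2)))
})

test_that("marginal BLUPs shrink correctly and solve the Henderson equations", {
  # zero genetic signal: identical genotype means -> all BLUPs ~ 0
  df <- toy_met_df(m = 4, p = 2, q = 2)
  set.seed(14)
  noise <- rnorm(4)
  df$y <- ave(seq_len(nrow(df)), df$env, df$block)  # pure block effects
  df$y <- df$y + rep(noise, each = 1)[rep(1:4, each = 4)] * 0  # no genotype term
  df$y <- df$y + rnorm(nrow(df), 0, 0.1)
  b <- marginal_blups(met_data(df))
  expect_lt(max(abs(b)), 0.2)

  # balanced one-environment case: BLUP_i = h (ybar_i - ybar)
  set.seed(15)
  df1 <- toy_met_df(m = 6, p = 1, q = 4)
  gm <- rnorm(6, sd = 2)
  df1$y <- gm[match(df1$gen, paste0("G", 1:6))] + rnorm(nrow(df1), 0, 0.7)
  # single environment, blocks B1..B4: fit with genotype random
  md1 <- met_data(df1)
  b1 <- marginal_blups(md1)
  fit <- lme4::lmer(y ~ 0 + factor(block) + (1 | gen), data = df1, REML = TRUE)
  vc <- lme4::VarCorr(fit)
  s2g <- as.numeric(vc$gen)
  s2e <- attr(vc, "sc")^2
  h <- s2g / (s2g + s2e / 4)
  # genotype means adjusted for block effects reduce to raw means in the
  # balanced case (every genotype sees every block)
  ybar <- as.numeric(tapply(df1$y, df1$gen, mean)[paste0("G", 1:6)])
  expect_equal(unname(b1), unname(h * (ybar - mean(ybar))), tolerance = 1e-6)

  # random balanced instance: dense Henderson-equations oracle at the same
  # variance components
  set.seed(16)
  df2 <- toy_met_df(m = 5, p = 2, q = 2)
  df2$y <- rnorm(nrow(df2), 10, 1) +
    rep(rnorm(5, sd = 1.5), each = 4)[match(df2$gen, df2$gen)] * 0 +
    rnorm(5, sd = 1.5)[match(df2$gen, paste0("G", 1:5))]
  md2 <- met_data(df2)
  b2 <- marginal_blups(md2)
  fit2 <- lme4::lmer(y ~ 0 + factor(paste(env, block)) + (1 | gen),
                     data = df2, REML = TRUE)
  vc2 <- lme4::VarCorr(fit2)
  lam <- attr(vc2, "sc")^2 / as.numeric(vc2$gen)
  dm <- build_design_matrices(md2)
  X <- dm$X1; Z <- dm$Zf
  lhs <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + lam * diag(5)))
  rhs <- c(crossprod(X, md2$records$value), crossprod(Z, md2$records$value))
  sol <- solve(lhs, rhs)
  expect_equal(unname(b2), unname(sol[(ncol(X) + 1):length(sol)]),
               tolerance = 1e-5)
})
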