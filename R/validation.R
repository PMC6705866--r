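#' Random cell-deletion fold plan
#'
#' Partitions the observed genotype x environment cells into `n_folds` folds of
#' (as near as possible) equal size for cell-deletion cross-validation: all
#' replicates of a deleted cell are withheld together. Every training set must
#' keep at least one cell in every environment and every genotype evaluated in
#' at least one environment; partitions violating the constraints are redrawn
#' (bounded retries) and an infeasible setup raises an error naming a limiting
#' genotype.
#'
#' @param data a `met_data` object.
#' @param n_folds number of folds (10, 3, 2 correspond to 10%, 33%, 50%
#'   deletion).
#' @param seed RNG seed; the plan is deterministic given the seed.
#' @param max_tries maximum partition redraws.
#' @return An object of class `bfa_folds`: a list of data.frames (`gen_id`,
#'   `env_id`, `gen`, `env`) plus the seed used.
#' @export
make_cell_folds <- function(data, n_folds, seed = 1, max_tries = 1000) {
  stopifnot(inherits(data, "met_data"), n_folds >= 2)
  obs <- which(data$cell_table > 0, arr.ind = TRUE)
  cells <- data.frame(gen_id = obs[, 1], env_id = obs[, 2])
  nc <- nrow(cells)
  if (nc < n_folds) stop("fewer observed cells than folds")

  gen_cells <- tabulate(cells$gen_id, nbins = data$m)
  env_cells <- tabulate(cells$env_id, nbins = data$p)

  set.seed(as.integer(seed))
  sizes <- rep(nc %/% n_folds, n_folds)
  extra <- nc %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold_of <- rep(seq_len(n_folds), times = sizes)

  for (try in seq_len(max_tries)) {
    perm <- sample.int(nc)
    assign <- integer(nc)
    assign[perm] <- fold_of
    ok <- TRUE
    for (fd in seq_len(n_folds)) {
      del <- assign == fd
      # training set = everything not in this fold
      if (any(gen_cells - tabulate(cells$gen_id[del], nbins = data$m) < 1) ||
          any(env_cells - tabulate(cells$env_id[del], nbins = data$p) < 1)) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      folds <- lapply(seq_len(n_folds), function(fd) {
        z <- cells[assign == fd, , drop = FALSE]
        z$gen <- data$genotypes[z$gen_id]
        z$env <- data$environments[z$env_id]
        rownames(z) <- NULL
        z
      })
      return(structure(list(folds = folds, n_folds = n_folds, seed = seed),
                       class = "bfa_folds"))
    }
  }
  scarce <- data$genotypes[which.min(gen_cells)]
  stop("could not build a feasible ", n_folds,
       "-fold cell-deletion plan in ", max_tries,
       " tries; genotype ", scarce, " is observed in only ",
       min(gen_cells), " cell(s)")
}

#' Predicted residual error sum of squares (mean form)
#'
#' `mean((observed - predicted)^2)` over withheld values.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return Scalar PRESS.
#' @export
press <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 1) stop("empty input")
  mean((observed - predicted)^2)
}

#' Pearson correlation between observed and predicted values
#'
#' @param observed,predicted equal-length numeric vectors (length >= 3).
#' @return Scalar correlation.
#' @export
prediction_correlation <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3) stop("at least 3 pairs are required")
  if (stats::var(observed) == 0 || stats::var(predicted) == 0) {
    stop("zero variance: the correlation is undefined")
  }
  stats::cor(observed, predicted)
}

#' Posterior-mean prediction of deleted genotype x environment cells
#'
#' For a deleted cell (i, j) the prediction is the posterior mean over retained
#' draws of the environment's fixed effect (averaged over its block cells, the
#' block identity of a deleted observation being undefined) plus the common
#' factor contribution `sum_k lambda_k alpha_jk f_ik` plus the specific effect
#' of the cell.
#'
#' @param chain a `bfa_chain` fitted to the training records.
#' @param cells data.frame with columns `gen` and `env` (names) identifying the
#'   deleted cells.
#' @return Numeric vector of predictions, one per row of `cells`.
#' @export
predict_deleted_cells <- function(chain, cells) {
  g <- match(as.character(cells$gen), chain$genotypes)
  e <- match(as.character(cells$env), chain$environments)
  if (anyNA(g)) stop("genotype absent from the training chain: ",
                     paste(unique(cells$gen[is.na(g)]), collapse = ", "))
  if (anyNA(e)) stop("environment absent from the training chain: ",
                     paste(unique(cells$env[is.na(e)]), collapse = ", "))
  K <- chain$config$k
  R <- chain$retained
  # per-draw environment fixed effect: average beta over the block cells
  env_id <- chain$eb_cells$env_id
  agg <- matrix(0, length(env_id), chain$p)
  agg[cbind(seq_along(env_id), env_id)] <- 1
  agg <- sweep(agg, 2, colSums(agg), "/")
  envfix <- chain$beta %*% agg          # R x p

  vapply(seq_len(nrow(cells)), function(i) {
    gi <- g[i]; ei <- e[i]
    gen_k <- rowSums(vapply(seq_len(K), function(k)
      chain$lambda[, k] * chain$alpha[, ei, k] * chain$f[, gi, k],
      numeric(R)))
    dcol <- (gi - 1L) * chain$p + ei
    mean(envfix[, ei] + gen_k + chain$delta[, dcol])
  }, numeric(1))
}

#' Statistical efficiency of a reduced-order model
#'
#' Ratio of the full model's PRESS to the candidate's PRESS; the full model has
#' efficiency 1 by definition, values above 1 favor the candidate.
#'
#' @param press_full PRESS of the full (k = p) model.
#' @param press_k PRESS of the candidate.
#' @return Scalar SE.
#' @export
statistical_efficiency <- function(press_full, press_k) {
  if (press_k <= 0 || press_full <= 0) stop("PRESS values must be positive")
  press_full / press_k
}

#' Monte Carlo AIC from posterior log-likelihood draws
#'
#' `AICM = 2 * (mean(l) - var(l))` over the retained per-draw log-likelihoods
#' (sample variance, N - 1 denominator). The preferred model is the one with
#' the highest AICM.
#'
#' @param loglik_draws numeric vector of per-draw log-likelihoods (>= 2).
#' @return Scalar AICM.
#' @export
aicm <- function(loglik_draws) {
  if (length(loglik_draws) < 2) stop("at least 2 log-likelihood draws required")
  2 * (mean(loglik_draws) - stats::var(loglik_draws))
}

#' Cell-deletion cross-validation of the factor analytic model
#'
#' Refits the model to each training set (the data minus one fold of deleted
#' cells), predicts the withheld cells by posterior means, and scores the
#' predictions against the observed cell means (the mean of a cell's withheld
#' replicates) with PRESS and the Pearson correlation, per fold and pooled.
#'
#' @param data a `met_data` object.
#' @param folds a [make_cell_folds()] plan, or a fold count to build one.
#' @param k number of factors; default full rank (k = p).
#' @param iterations,burn_in,thin per-fold chain settings (shorter than
#'   headline fits; each fold is an independent refit).
#' @param seed base seed; fold i uses `seed + i`.
#' @param priors a [bfa_priors()].
#' @return An object of class `bfa_cv`: per-fold table (`fold`, `n_cells`,
#'   `press`, `correlation`), pooled `press` and `correlation`, and the
#'   per-cell predictions.
#' @export
run_cv <- function(data, folds, k = data$p, iterations = 6000, burn_in = 1000,
                   thin = 2, seed = 1, priors = bfa_priors()) {
  if (!inherits(folds, "bfa_folds")) {
    folds <- make_cell_folds(data, n_folds = folds, seed = seed)
  }
  cell_means <- function(cells) {
    vapply(seq_len(nrow(cells)), function(i) {
      sel <- data$records$gen_id == cells$gen_id[i] &
        data$records$env_id == cells$env_id[i]
      mean(data$records$value[sel])
    }, numeric(1))
  }
  preds <- vector("list", folds$n_folds)
  for (fd in seq_len(folds$n_folds)) {
    cells <- folds$folds[[fd]]
    train <- met_drop_cells(data, cells)
    chain <- bfa_fit(train, k = k, iterations = iterations, burn_in = burn_in,
                     thin = thin, seed = as.integer(seed) + fd, priors = priors)
    preds[[fd]] <- data.frame(fold = fd, gen = cells$gen, env = cells$env,
                              observed = cell_means(cells),
                              predicted = predict_deleted_cells(chain, cells))
  }
  all_pred <- do.call(rbind, preds)
  per_fold <- do.call(rbind, lapply(preds, function(z) data.frame(
    fold = z$fold[1], n_cells = nrow(z),
    press = press(z$observed, z$predicted),
    correlation = prediction_correlation(z$observed, z$predicted))))
  structure(list(per_fold = per_fold,
                 press = press(all_pred$observed, all_pred$predicted),
                 correlation = prediction_correlation(all_pred$observed,
                                                      all_pred$predicted),
                 predictions = all_pred, n_folds = folds$n_folds,
                 k = k, seed = seed),
            class = "bfa_cv")
}

#' @export
print.bfa_cv <- function(x, ...) {
  cat("Cell-deletion cross-validation (", x$n_folds, " folds, k = ", x$k,
      ")\n", sep = "")
  cat(sprintf("pooled PRESS %.4f, pooled observed-vs-predicted correlation %.3f\n",
              x$press, x$correlation))
  print(x$per_fold, row.names = FALSE)
  invisible(x)
}

#' Select the number of factors by cross-validation and AICM
#'
#' Fits every candidate order on the same fold plan, reporting pooled PRESS,
#' pooled predictive correlation, statistical efficiency (PRESS of the full
#' model over the candidate's; requires the full order among the candidates),
#' AICM from a full-data fit per order, and per-criterion ranks. Criteria may
#' disagree; no single winner is forced.
#'
#' @param data a `met_data` object.
#' @param orders candidate factor counts (subset of 1..p).
#' @param n_folds folds for the shared cross-validation plan.
#' @param seed seed for the fold plan and fits.
#' @param iterations,burn_in,thin chain settings for both the CV fits and the
#'   full-data AICM fits.
#' @param priors a [bfa_priors()].
#' @return data.frame with one row per order: `k`, `press`, `correlation`,
#'   `se`, `aicm`, `delta_aicm` and rank columns.
#' @export
select_k <- function(data, orders = seq_len(data$p), n_folds = 10, seed = 1,
                     iterations = 6000, burn_in = 1000, thin = 2,
                     priors = bfa_priors()) {
  stopifnot(all(orders >= 1), all(orders <= data$p))
  orders <- sort(unique(as.integer(orders)))
  folds <- make_cell_folds(data, n_folds = n_folds, seed = seed)
  rows <- lapply(orders, function(k) {
    cv <- run_cv(data, folds, k = k, iterations = iterations,
                 burn_in = burn_in, thin = thin, seed = seed, priors = priors)
    fit <- bfa_fit(data, k = k, iterations = iterations, burn_in = burn_in,
                   thin = thin, seed = seed, priors = priors)
    data.frame(k = k, press = cv$press, correlation = cv$correlation,
               aicm = aicm(fit$loglik))
  })
  out <- do.call(rbind, rows)
  full <- out$press[out$k == data$p]
  out$se <- if (length(full) == 1) full / out$press else NA_real_
  full_aicm <- out$aicm[out$k == data$p]
  out$delta_aicm <- if (length(full_aicm) == 1) full_aicm - out$aicm else NA_real_
  out$rank_press <- rank(out$press, ties.method = "min")
  out$rank_correlation <- rank(-out$correlation, ties.method = "min")
  out$rank_se <- rank(-out$se, ties.method = "min")
  out$rank_aicm <- rank(-out$aicm, ties.method = "min")
  out
}

#' Marginal genotype BLUPs from the two-way mixed model
#'
#' Fits the baseline mixed model (fixed environment-block cell means, a single
#' random genotype effect, homogeneous residual) by REML and returns the
#' shrunken genotype effects. Used to benchmark the first-factor posterior-mean
#' scores: when the main genotype effect is confounded with the interaction,
#' the first factor's scores track these marginal BLUPs.
#'
#' @param data a `met_data` object with at least 2 genotypes.
#' @return Named numeric vector of predicted genotype effects (order of
#'   `data$genotypes`). All zeros when the genotype variance is estimated at
#'   zero.
#' @export
marginal_blups <- function(data) {
  stopifnot(inherits(data, "met_data"))
  if (data$m < 2) stop("at least 2 genotypes are required")
  df <- data.frame(y = data$records$value,
                   cell = factor(data$records$eb),
                   gen = factor(data$records$gen_id, levels = seq_len(data$m)))
  fit <- suppressMessages(lme4::lmer(
    y ~ 0 + cell + (1 | gen), data = df, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  re <- lme4::ranef(fit)$gen
  out <- numeric(data$m)
  out[as.integer(rownames(re))] <- re[, 1]
  names(out) <- data$genotypes
  out
}
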