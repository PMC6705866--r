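#' Design of a simulated multi-environment trial
#'
#' Describes a randomized complete block MET with three genotype stability
#' groups: positive-unstable genotypes (positive marginal effect, large
#' interaction variance), negative-unstable genotypes (negative marginal
#' effect, large interaction variance) and stable genotypes (zero marginal
#' effect, standard-Gaussian interactions). Residual variances are
#' heterogeneous across environments. The defaults are 20 genotypes (5/5/10
#' across the groups) in 5 environments with 2 replicates, marginal effects of
#' +/-2.5 trait units for the unstable groups (calibrated to the scale of the
#' reference design's first-axis loading products), interaction variances 2
#' (unstable) and 1 (stable), and per-environment residual variances
#' (0.546, 1.209, 4.690, 7.377, 9.026).
#'
#' @param m,p,q genotype, environment and replicate (block) counts.
#' @param groups sizes of the (positive-unstable, negative-unstable, stable)
#'   groups; must sum to `m`.
#' @param marginal marginal-effect means (trait units) of the three groups;
#'   each genotype's marginal effect is a Gaussian realization around its
#'   group's mean.
#' @param marginal_sd standard deviation of the marginal-effect draws
#'   (standard Gaussian by default).
#' @param interaction_var interaction variances of the three groups.
#' @param sigma_e2 per-environment residual variances (length `p`).
#' @param env_block_effects fixed effect per environment-block cell: a scalar
#'   or a p x q matrix. Default 0.
#' @return An object of class `bfa_sim_design`.
#' @export
simulation_design <- function(m = 20, p = 5, q = 2,
                              groups = c(5, 5, 10),
                              marginal = c(2.5, -2.5, 0),
                              marginal_sd = 1,
                              interaction_var = c(2, 2, 1),
                              sigma_e2 = c(0.546, 1.209, 4.690, 7.377, 9.026),
                              env_block_effects = 0) {
  if (sum(groups) != m) stop("group sizes must sum to m")
  if (length(sigma_e2) != p) stop("sigma_e2 must have one entry per environment")
  if (any(sigma_e2 < 0) || any(interaction_var < 0) || marginal_sd < 0) {
    stop("variances must be nonnegative")
  }
  stopifnot(length(groups) == 3, length(marginal) == 3,
            length(interaction_var) == 3, q >= 1)
  eb <- matrix(env_block_effects, p, q)
  structure(list(m = m, p = p, q = q, groups = as.integer(groups),
                 marginal = marginal, marginal_sd = marginal_sd,
                 interaction_var = interaction_var,
                 sigma_e2 = sigma_e2, env_block_effects = eb),
            class = "bfa_sim_design")
}

#' Simulate a multi-environment trial with known genetic structure
#'
#' Each genotype draws a marginal effect (Gaussian around its group's mean)
#' plus independent per-environment Gaussian interaction deviations with the
#' group's variance;
#' an observation is the environment-block fixed effect plus the genotype's
#' total genetic effect in that environment plus Gaussian noise with the
#' environment's residual variance. The layout is complete (`m * p * q`
#' records) and the realization is deterministic given the seed.
#'
#' @param design a [simulation_design()].
#' @param seed RNG seed.
#' @return List with `data` (a [met_data()]) and `truth`: the realized marginal
#'   effects, interaction matrix, total genetic effects (m x p), the design
#'   residual variances, the population-implied genetic covariance across
#'   environments, the realized (sample) genetic covariance, and the realized
#'   loading products `tau` from its spectral decomposition (columns
#'   `sqrt(eigenvalue) * eigenvector`, first axis sign-aligned positive).
#' @export
simulate_met <- function(design = simulation_design(), seed = 1) {
  stopifnot(inherits(design, "bfa_sim_design"))
  set.seed(as.integer(seed))
  m <- design$m; p <- design$p; q <- design$q
  grp <- rep(1:3, times = design$groups)
  marg <- stats::rnorm(m, design$marginal[grp], design$marginal_sd)
  ivar <- design$interaction_var[grp]
  inter <- matrix(stats::rnorm(m * p, 0, rep(sqrt(ivar), p)), m, p)
  u <- marg + inter

  genotypes <- paste0("G", seq_len(m))
  environments <- paste0("E", seq_len(p))
  rec <- expand.grid(block = paste0("B", seq_len(q)),
                     env_id = seq_len(p), gen_id = seq_len(m),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  noise <- stats::rnorm(nrow(rec), 0, sqrt(design$sigma_e2[rec$env_id]))
  block_id <- match(rec$block, paste0("B", seq_len(q)))
  rec$y <- design$env_block_effects[cbind(rec$env_id, block_id)] +
    u[cbind(rec$gen_id, rec$env_id)] + noise
  df <- data.frame(gen = genotypes[rec$gen_id], env = environments[rec$env_id],
                   block = rec$block, y = rec$y, stringsAsFactors = FALSE)
  df <- df[order(rec$gen_id, rec$env_id, block_id), ]
  rownames(df) <- NULL
  data <- met_data(df)

  # population covariance across environments of the genetic effects:
  # between-group variance of the marginals on all pairs, plus the average
  # interaction variance on the diagonal
  w <- design$groups / m
  v_between <- design$marginal_sd^2 +
    sum(w * design$marginal^2) - sum(w * design$marginal)^2
  v_within <- sum(w * design$interaction_var)
  Sigma_implied <- matrix(v_between, p, p) + diag(v_within, p)

  Sigma_realized <- stats::cov(u)
  eg <- eigen((Sigma_realized + t(Sigma_realized)) / 2, symmetric = TRUE)
  tau <- vapply(seq_len(p), function(k) {
    v <- sqrt(max(eg$values[k], 0)) * eg$vectors[, k]
    if (sum(v) < 0) -v else v
  }, numeric(p))

  s2_real <- as.numeric(tapply(noise, rec$env_id, stats::var))

  truth <- list(group = grp, marginal = marg, interaction = inter,
                genetic = u, sigma_e2 = design$sigma_e2,
                sigma_e2_realized = s2_real,
                Sigma_implied = Sigma_implied, Sigma_realized = Sigma_realized,
                tau = tau)
  list(data = data, truth = truth)
}

#' Delete genotype x environment cells from a dataset
#'
#' Removes all replicates of the selected cells. With a numeric fraction the
#' cells are drawn at random subject to the cross-validation constraints
#' (every environment keeps a cell, every genotype stays evaluated somewhere);
#' with a fold from [make_cell_folds()] the fold's cells are removed.
#'
#' @param data a `met_data` object.
#' @param what a deletion fraction in `[0, 1)`, or a data.frame of cells with
#'   `gen_id`/`env_id` columns (e.g. one element of a `bfa_folds` plan).
#' @param seed RNG seed for fractional deletion.
#' @return A `met_data` with the cells removed (identical dataset for
#'   fraction 0).
#' @export
apply_missingness <- function(data, what, seed = 1) {
  stopifnot(inherits(data, "met_data"))
  if (is.numeric(what) && length(what) == 1) {
    if (what < 0 || what >= 1) stop("deletion fraction must be in [0, 1)")
    if (what == 0) return(data)
    n_obs <- sum(data$cell_table > 0)
    n_del <- round(what * n_obs)
    if (n_del == 0) return(data)
    n_folds <- max(2L, as.integer(round(n_obs / n_del)))
    plan <- make_cell_folds(data, n_folds = n_folds, seed = seed)
    cells <- plan$folds[[1]][seq_len(n_del), , drop = FALSE]
  } else {
    cells <- what
    stopifnot(is.data.frame(cells), all(c("gen_id", "env_id") %in% names(cells)))
  }
  met_drop_cells(data, cells)
}
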