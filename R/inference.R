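#' HPD-based posterior mode (MAP) estimate
#'
#' Chen-Shao style mode estimate: the midpoint of the shortest interval
#' containing a small fixed fraction of the sorted draws. With a unimodal
#' posterior the shortest dense window sits at the mode.
#'
#' @param draws numeric vector of posterior draws (at least 100).
#' @param frac fraction of draws in the window (default 0.05).
#' @return Scalar estimate.
#' @export
map_estimate <- function(draws, frac = 0.05) {
  draws <- as.numeric(draws)
  if (length(draws) < 100) stop("at least 100 draws are required")
  stopifnot(frac > 0, frac < 1)
  x <- sort(draws)
  n <- length(x)
  w <- max(2L, as.integer(ceiling(frac * n)))
  i <- seq_len(n - w + 1L)
  widths <- x[i + w - 1L] - x[i]
  j <- which.min(widths)   # ties resolve to the lowest start
  (x[j] + x[j + w - 1L]) / 2
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(prob * N)` of the sorted
#' draws; ties resolve to the lowest start.
#'
#' @param draws numeric vector of posterior draws (at least 100).
#' @param prob coverage probability in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  draws <- as.numeric(draws)
  if (length(draws) < 100) stop("at least 100 draws are required")
  stopifnot(prob > 0, prob < 1)
  x <- sort(draws)
  n <- length(x)
  w <- min(n, as.integer(ceiling(prob * n)))
  i <- seq_len(n - w + 1L)
  j <- which.min(x[i + w - 1L] - x[i])
  c(lower = x[j], upper = x[j + w - 1L])
}

#' Bivariate credibility region for a pair of posterior draw sequences
#'
#' Computes the Euclidean distance of every (x, y) draw to the distribution
#' center (the coordinatewise posterior mean), discards the farthest
#' `1 - prob` fraction, and returns the retained points together with their
#' convex hull as the region boundary. A region that does not contain the
#' biplot origin flags a coordinate pair credibly different from zero.
#'
#' @param draws_x,draws_y paired draw sequences (at least 100 points).
#' @param prob coverage probability.
#' @return An object of class `bfa_region`: `center`, `retained` (points kept),
#'   `hull` (polygon vertices, closed implicitly), `prob`, `contains_origin`,
#'   and the polygon `area`.
#' @export
credible_region_2d <- function(draws_x, draws_y, prob = 0.95) {
  stopifnot(length(draws_x) == length(draws_y))
  n <- length(draws_x)
  if (n < 100) stop("at least 100 points are required")
  pts <- cbind(x = as.numeric(draws_x), y = as.numeric(draws_y))
  ctr <- colMeans(pts)
  d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  keep_n <- as.integer(ceiling(prob * n))
  keep <- order(d)[seq_len(keep_n)]
  retained <- pts[keep, , drop = FALSE]

  degenerate <- max(d) == 0
  if (degenerate) {
    hull <- retained[1, , drop = FALSE]
    area <- 0
    contains <- all(retained[1, ] == 0)
  } else {
    h <- grDevices::chull(retained)
    hull <- retained[h, , drop = FALSE]
    area <- polygon_area(hull)
    contains <- point_in_convex_polygon(c(0, 0), hull)
  }
  structure(list(center = ctr, retained = retained, hull = hull,
                 prob = prob, contains_origin = contains, area = area),
            class = "bfa_region")
}

#' @export
print.bfa_region <- function(x, ...) {
  cat(sprintf("%.0f%% credibility region: center (%.3f, %.3f), %d points retained, area %.4g, %s the origin\n",
              100 * x$prob, x$center[1], x$center[2], nrow(x$retained), x$area,
              if (x$contains_origin) "contains" else "excludes"))
  invisible(x)
}

# shoelace area of a polygon given by its vertices in order
polygon_area <- function(v) {
  if (nrow(v) < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# point-in-convex-polygon via consistent cross-product signs (boundary counts)
point_in_convex_polygon <- function(pt, v) {
  nv <- nrow(v)
  if (nv == 1) return(all(pt == v[1, ]))
  if (nv == 2) {
    # degenerate segment
    d <- v[2, ] - v[1, ]
    w <- pt - v[1, ]
    crossp <- d[1] * w[2] - d[2] * w[1]
    if (abs(crossp) > 1e-12 * (sum(abs(d)) + 1)) return(FALSE)
    t <- if (abs(d[1]) >= abs(d[2])) w[1] / d[1] else w[2] / d[2]
    return(t >= 0 && t <= 1)
  }
  sgn <- numeric(nv)
  for (i in seq_len(nv)) {
    a <- v[i, ]
    b <- v[if (i == nv) 1 else i + 1, ]
    sgn[i] <- (b[1] - a[1]) * (pt[2] - a[2]) - (b[2] - a[2]) * (pt[1] - a[1])
  }
  all(sgn >= 0) || all(sgn <= 0)
}

#' Geweke convergence z-score
#'
#' Difference of means between an early and a late window of the chain,
#' standardized by spectral-density variance estimates.
#'
#' @param draws numeric chain (at least 200 draws).
#' @param first,last fractions of the chain in the early and late windows.
#' @return Scalar z-score.
#' @export
geweke_z <- function(draws, first = 0.1, last = 0.5) {
  draws <- as.numeric(draws)
  if (length(draws) < 200) stop("at least 200 draws are required")
  if (first + last > 1) stop("first and last windows overlap")
  if (stats::var(draws) == 0) {
    stop("degenerate (constant) chain: the Geweke z-score is undefined")
  }
  z <- coda::geweke.diag(coda::mcmc(draws), frac1 = first, frac2 = last)$z
  unname(z)
}

#' Heidelberger-Welch stationarity and halfwidth diagnostic
#'
#' Cramer-von Mises stationarity scan (discarding successive 10% prefixes)
#' plus the 95% halfwidth test.
#'
#' @param draws numeric chain.
#' @param eps halfwidth tolerance (ratio of the halfwidth to the mean).
#' @param pvalue stationarity test level.
#' @return List with `stationarity` (logical), `start` (1-based index of the
#'   usable part), `halfwidth_passed` and `halfwidth_ratio`.
#' @export
heidelberger_welch <- function(draws, eps = 0.1, pvalue = 0.05) {
  draws <- as.numeric(draws)
  if (stats::var(draws) == 0) {
    stop("degenerate (constant) chain: the stationarity test is undefined")
  }
  h <- coda::heidel.diag(coda::mcmc(draws), eps = eps, pvalue = pvalue)
  ratio <- unname(h[1, "halfwidth"] / abs(h[1, "mean"]))
  list(stationarity = isTRUE(h[1, "stest"] == 1),
       start = as.integer(h[1, "start"]),
       halfwidth_passed = isTRUE(h[1, "htest"] == 1),
       halfwidth_ratio = ratio)
}

#' Raftery-Lewis run-length diagnostic
#'
#' Two-state Markov chain analysis of the thresholded chain for estimating the
#' burn-in, required chain length and dependence factor I for a posterior
#' quantile.
#'
#' @param draws numeric chain.
#' @param q quantile of interest.
#' @param r desired precision.
#' @param s probability of attaining the precision.
#' @return List with `burn_in`, `required_n` and `dependence_factor`.
#' @export
raftery_lewis <- function(draws, q = 0.025, r = 0.005, s = 0.95) {
  draws <- as.numeric(draws)
  n_min <- ceiling(stats::qnorm(0.5 * (1 + s))^2 * q * (1 - q) / r^2)
  if (length(draws) < n_min) {
    stop("chain too short for the pilot estimate: ", length(draws),
         " draws, at least ", n_min, " required")
  }
  rl <- coda::raftery.diag(coda::mcmc(draws), q = q, r = r, s = s)
  res <- rl$resmatrix
  list(burn_in = unname(res[1, "M"]), required_n = unname(res[1, "N"]),
       dependence_factor = unname(res[1, "I"]))
}

# posterior-mean loading products per factor: R x p x k array of lambda_k alpha_k
loading_draws <- function(chain, k) {
  chain$lambda[, k] * chain$alpha[, , k]
}

#' Variance-partition diagnostic of a fitted chain
#'
#' At the posterior mean of the loading products, specific variances and
#' residual variances, reports the geometric means over environments of the
#' per-environment genetic variance carried by the loadings `diag(Gamma
#' Gamma')`, the total genetic variance `diag(Gamma Gamma' + Psi)`, the
#' specific variances and the residual variances. In a full-rank fit the
#' specific variances are identically zero and the loadings carry all of the
#' genetic variance.
#'
#' @param chain a `bfa_chain`.
#' @return List with `genetic_loadings`, `genetic_total`, `specific`,
#'   `residual` (geometric means) and the underlying per-environment vectors.
#' @export
variance_partition <- function(chain) {
  K <- chain$config$k
  p <- chain$p
  Gamma <- vapply(seq_len(K), function(k) colMeans(loading_draws(chain, k)),
                  numeric(p))
  g_load <- rowSums(Gamma^2)
  psi_pm <- colMeans(chain$psi)
  s2_pm <- colMeans(chain$sigma_e2)
  gm <- function(v) if (any(v == 0)) 0 else exp(mean(log(v)))
  list(genetic_loadings = gm(g_load), genetic_total = gm(g_load + psi_pm),
       specific = gm(psi_pm), residual = gm(s2_pm),
       per_environment = list(genetic_loadings = g_load,
                              psi = psi_pm, sigma_e2 = s2_pm))
}

#' Biplot coordinates with bivariate credibility regions
#'
#' Posterior-mean loading products (lambda_1 alpha_1, lambda_2 alpha_2) per
#' environment and factor scores (f_1, f_2) per genotype on two factor axes,
#' each with its [credible_region_2d()]. Draws are sign-aligned at sampling
#' time, so the coordinates are invariant to the sign ambiguity of the factors.
#' When all first-axis loadings are positive, the main genotype effect is
#' confounded with the interaction on axis 1 and the display reads like a
#' GGE-biplot.
#'
#' @param chain a `bfa_chain` fitted with at least two factors.
#' @param axes which two factors to display.
#' @param prob region coverage probability.
#' @return List with data frames `loadings` (environment coordinates) and
#'   `scores` (genotype coordinates), region lists `loading_regions` and
#'   `score_regions`, and `gge_like` (all first-axis loadings positive).
#' @export
biplot_coordinates <- function(chain, axes = c(1, 2), prob = 0.95) {
  if (chain$config$k < 2) stop("at least two factors are required for a biplot")
  stopifnot(length(axes) == 2, all(axes %in% seq_len(chain$config$k)))
  L1 <- loading_draws(chain, axes[1])
  L2 <- loading_draws(chain, axes[2])
  F1 <- chain$f[, , axes[1], drop = TRUE]
  F2 <- chain$f[, , axes[2], drop = TRUE]

  loadings <- data.frame(environment = chain$environments,
                         x = colMeans(L1), y = colMeans(L2))
  scores <- data.frame(genotype = chain$genotypes,
                       x = colMeans(F1), y = colMeans(F2))
  loading_regions <- lapply(seq_len(chain$p), function(j)
    credible_region_2d(L1[, j], L2[, j], prob))
  names(loading_regions) <- chain$environments
  score_regions <- lapply(seq_len(chain$m), function(i)
    credible_region_2d(F1[, i], F2[, i], prob))
  names(score_regions) <- chain$genotypes

  list(loadings = loadings, scores = scores,
       loading_regions = loading_regions, score_regions = score_regions,
       gge_like = all(loadings$x > 0))
}

#' Posterior summary table of a fitted chain
#'
#' Posterior mean, posterior standard deviation, HPD-mode MAP estimate and 95%
#' HPD limits for the residual variances, specific variances, singular values
#' and loading products.
#'
#' @param object a `bfa_chain`.
#' @param prob HPD coverage probability.
#' @param ... unused.
#' @return data.frame with columns parameter, PM, PSD, MAP, LL, UL.
#' @export
summary.bfa_chain <- function(object, prob = 0.95, ...) {
  rows <- list()
  add <- function(name, draws) {
    h <- hpd_interval(draws, prob)
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = name, PM = mean(draws), PSD = stats::sd(draws),
      MAP = map_estimate(draws), LL = h[["lower"]], UL = h[["upper"]])
  }
  for (j in seq_len(object$p)) {
    add(paste0("sigma_e2[", object$environments[j], "]"), object$sigma_e2[, j])
  }
  if (!object$full_rank) {
    for (j in seq_len(object$p)) {
      add(paste0("psi[", object$environments[j], "]"), object$psi[, j])
    }
  }
  for (k in seq_len(object$config$k)) {
    add(paste0("lambda[", k, "]"), object$lambda[, k])
  }
  for (k in seq_len(min(2L, object$config$k))) {
    L <- loading_draws(object, k)
    for (j in seq_len(object$p)) {
      add(paste0("tau", k, "[", object$environments[j], "]"), L[, j])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
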