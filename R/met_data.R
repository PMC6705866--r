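#' Construct a multi-environment trial dataset
#'
#' Validates and indexes long-format phenotype records (one row per plot) for
#' use with the Bayesian factor analytic model. Each record is a trait
#' measurement on one genotype in one block of one environment; blocks are
#' nested within environments. Genotype x environment cells may be missing
#' (unbalanced trials), but every genotype and every environment must carry at
#' least one record, otherwise its effects are not estimable.
#'
#' @param df data.frame with one row per plot.
#' @param gen,env,block,value names of the genotype, environment, block and
#'   trait-value columns. `block` may be `NULL` for unreplicated data (a single
#'   block "B1" per environment is assumed).
#' @return An object of class `met_data`: the validated records (with 1-based
#'   integer indices attached), the genotype/environment/block index sets, the
#'   counts `m` (genotypes), `p` (environments), `q` (maximum blocks per
#'   environment), `n` (records), the occurring environment-block cells, and
#'   the `cell_table` of replicate counts per genotype x environment cell.
#' @examples
#' df <- expand.grid(gen = c("G1", "G2"), env = c("E1", "E2"), block = c("B1", "B2"))
#' df$y <- rnorm(nrow(df))
#' md <- met_data(df, value = "y")
#' md$cell_table
#' @export
met_data <- function(df, gen = "gen", env = "env", block = "block", value = "y") {
  if (!is.data.frame(df)) stop("`df` must be a data.frame")
  need <- c(gen = gen, env = env, value = value)
  if (!is.null(block)) need <- c(need, block = block)
  missing_cols <- setdiff(unname(need), names(df))
  if (length(missing_cols) > 0) {
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "))
  }
  y <- df[[value]]
  if (!is.numeric(y)) {
    bad <- suppressWarnings(which(is.na(as.numeric(as.character(y)))))
    stop("trait value column '", value, "' is not numeric (first offending row: ",
         if (length(bad)) bad[1] else 1, ")")
  }
  if (any(!is.finite(y))) {
    stop("non-finite trait value at row(s): ",
         paste(utils::head(which(!is.finite(y)), 5), collapse = ", "))
  }

  # factor inputs may carry declared-but-unused levels: a genotype or
  # environment with zero records is not estimable
  for (nm in c(gen, env)) {
    if (is.factor(df[[nm]])) {
      unused <- setdiff(levels(df[[nm]]), as.character(unique(df[[nm]])))
      if (length(unused) > 0) {
        stop(if (nm == gen) "genotype(s) " else "environment(s) ",
             paste(unused, collapse = ", "), " declared but appear in no record")
      }
    }
  }

  g_chr <- as.character(df[[gen]])
  e_chr <- as.character(df[[env]])
  b_chr <- if (is.null(block)) rep("B1", nrow(df)) else as.character(df[[block]])

  # factor inputs fix the index order via their levels; otherwise first appearance
  genotypes    <- if (is.factor(df[[gen]])) levels(df[[gen]]) else unique(g_chr)
  environments <- if (is.factor(df[[env]])) levels(df[[env]]) else unique(e_chr)
  m <- length(genotypes)
  p <- length(environments)
  gid <- match(g_chr, genotypes)
  eid <- match(e_chr, environments)

  trip <- paste(g_chr, e_chr, b_chr, sep = "\r")
  if (anyDuplicated(trip)) {
    d <- trip[duplicated(trip)][1]
    stop("duplicate (genotype, environment, block) triple: (",
         gsub("\r", ", ", d, fixed = TRUE), ")")
  }

  # occurring environment-block cells, in order of first appearance
  eb_key <- paste(eid, b_chr, sep = "\r")
  eb_levels <- unique(eb_key)
  eb <- match(eb_key, eb_levels)
  eb_split <- strsplit(eb_levels, "\r", fixed = TRUE)
  eb_cells <- data.frame(
    env_id = vapply(eb_split, function(z) as.integer(z[1]), integer(1)),
    block  = vapply(eb_split, function(z) z[2], character(1)),
    stringsAsFactors = FALSE
  )
  eb_cells$label <- paste(environments[eb_cells$env_id], eb_cells$block, sep = ":")
  q <- max(tabulate(eb_cells$env_id, nbins = p))

  records <- data.frame(
    gen = g_chr, env = e_chr, block = b_chr, value = as.numeric(y),
    gen_id = gid, env_id = eid, eb = eb,
    ge = (gid - 1L) * p + eid,
    stringsAsFactors = FALSE
  )

  cell_table <- matrix(0L, m, p, dimnames = list(genotypes, environments))
  tb <- table(factor(gid, levels = seq_len(m)), factor(eid, levels = seq_len(p)))
  cell_table[] <- as.integer(tb)

  out <- structure(
    list(records = records, m = m, p = p, q = q, n = nrow(records),
         genotypes = genotypes, environments = environments,
         eb_cells = eb_cells, cell_table = cell_table),
    class = "met_data"
  )
  # precomputed index bundle for the sampler hot path
  out$idx <- list(y = records$value, e = records$env_id, g = records$gen_id,
                  eb = records$eb, ge = records$ge, n = out$n, m = m, p = p,
                  n_eb = nrow(eb_cells), eb_env = eb_cells$env_id,
                  cell_env = rep(seq_len(p), times = m),
                  cnt_eb = tabulate(records$eb, nbins = nrow(eb_cells)),
                  cnt_ge = tabulate(records$ge, nbins = m * p),
                  n_env = tabulate(records$env_id, nbins = p))
  out
}

#' Read a multi-environment trial from a CSV file
#'
#' Reads a long-format phenotype table (comma-separated, header row) and
#' validates it with [met_data()]. Column names `gen`, `env`, `rep`/`block`
#' and `y` are auto-detected; anything else requires the explicit arguments.
#'
#' @param path path to the CSV file.
#' @param gen_col,env_col,block_col,value_col column names; `NULL` means
#'   auto-detect.
#' @return A [met_data()] object. The row order of the file is preserved.
#' @export
read_met_csv <- function(path, gen_col = NULL, env_col = NULL,
                         block_col = NULL, value_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pick <- function(given, candidates, what, required = TRUE) {
    if (!is.null(given)) {
      if (!given %in% names(df)) stop("column '", given, "' not found in ", path)
      return(given)
    }
    hit <- intersect(candidates, names(df))
    if (length(hit) == 0) {
      if (required) stop("could not auto-detect the ", what,
                         " column in ", path, "; pass it explicitly")
      return(NULL)
    }
    hit[1]
  }
  gen_col   <- pick(gen_col,   c("gen", "genotype", "Gen"), "genotype")
  env_col   <- pick(env_col,   c("env", "environment", "Env"), "environment")
  block_col <- pick(block_col, c("rep", "block", "Rep", "Block"), "block",
                    required = FALSE)
  value_col <- pick(value_col, c("y", "value", "yield", "Y"), "trait value")
  met_data(df, gen = gen_col, env = env_col, block = block_col, value = value_col)
}

#' Write a multi-environment trial dataset to CSV
#'
#' Writes the canonical long format (`gen`, `env`, `block`, `y`), preserving
#' record order so that a write/read round trip reproduces the same dataset
#' and index maps.
#'
#' @param data a `met_data` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_met_csv <- function(data, path) {
  stopifnot(inherits(data, "met_data"))
  out <- data$records[, c("gen", "env", "block", "value")]
  names(out) <- c("gen", "env", "block", "y")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.met_data <- function(x, ...) {
  cat("Multi-environment trial: ", x$n, " records, ",
      x$m, " genotypes x ", x$p, " environments (<= ", x$q,
      " blocks/environment)\n", sep = "")
  miss <- sum(x$cell_table == 0)
  cat("observed cells: ", sum(x$cell_table > 0), " of ", x$m * x$p,
      if (miss > 0) paste0(" (", miss, " missing)"), "\n", sep = "")
  invisible(x)
}

#' Summarize a MET dataset
#'
#' @param object a `met_data` object.
#' @param ... unused.
#' @return A list with record/genotype/environment counts, per-environment
#'   record counts and missing-cell counts. Serializes naturally to JSON.
#' @export
summary.met_data <- function(object, ...) {
  per_env <- tabulate(object$records$env_id, nbins = object$p)
  names(per_env) <- object$environments
  miss_env <- colSums(object$cell_table == 0)
  list(n = object$n, m = object$m, p = object$p, q = object$q,
       records_per_environment = as.list(per_env),
       missing_cells_per_environment = as.list(miss_env),
       observed_cells = sum(object$cell_table > 0))
}

#' Build the design matrices of the summation-form factor analytic model
#'
#' Constructs the four incidence matrices that distribute the model effects
#' over the observations: `X1` (environment-block fixed-effect cells, one
#' column per occurring cell), `X2` (environments), `Z` (genotype x
#' environment cells, carrying the specific effects), and `Zf` (genotypes).
#' Row i of every matrix corresponds to record i; each row contains a single 1.
#'
#' @param data a `met_data` object.
#' @return An object of class `met_design` with elements `X1` (n x n_eb),
#'   `X2` (n x p), `Z` (n x mp), `Zf` (n x m).
#' @export
build_design_matrices <- function(data) {
  stopifnot(inherits(data, "met_data"))
  r <- data$records
  n <- data$n
  ind <- function(idx, ncol, colnames) {
    M <- matrix(0, n, ncol, dimnames = list(NULL, colnames))
    M[cbind(seq_len(n), idx)] <- 1
    M
  }
  ge_names <- as.vector(t(outer(data$genotypes, data$environments, paste, sep = ":")))
  structure(
    list(
      X1 = ind(r$eb, nrow(data$eb_cells), data$eb_cells$label),
      X2 = ind(r$env_id, data$p, data$environments),
      Z  = ind(r$ge, data$m * data$p, ge_names),
      Zf = ind(r$gen_id, data$m, data$genotypes)
    ),
    class = "met_design"
  )
}

# Training subset of a met_data: drop all records of the given
# genotype x environment cells (data.frame with gen_id, env_id columns).
# Index maps of the parent are preserved by reusing the parent's level order.
met_drop_cells <- function(data, cells) {
  stopifnot(inherits(data, "met_data"))
  drop_ge <- (cells$gen_id - 1L) * data$p + cells$env_id
  keep <- !(data$records$ge %in% drop_ge)
  rec <- data$records[keep, c("gen", "env", "block", "value")]
  rec$gen <- factor(rec$gen, levels = data$genotypes)
  rec$env <- factor(rec$env, levels = data$environments)
  met_data(rec, gen = "gen", env = "env", block = "block", value = "value")
}
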