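#' Per-replicate demeaned fluctuation series
#'
#' Within each replicate, subtracts every OTU's temporal mean from its
#' relative-abundance series, so replicate-level offsets cannot masquerade
#' as temporal co-variation. The demeaned replicate blocks are concatenated
#' in replicate order.
#'
#' @param rel a `relative_abundance_table` (see [to_relative_abundance()]);
#'   at least 2 time steps per replicate.
#' @return matrix `n_otus x n_samples` of fluctuations, with attributes
#'   `replicates` and `time_steps`; each OTU's fluctuations sum to zero
#'   within every replicate.
#' @export
fluctuation_series <- function(rel) {
  stopifnot(inherits(rel, "relative_abundance_table"))
  if (max(rel$time_steps) < 2L)
    stop("fluctuations need at least 2 time steps")
  fl <- rel$values
  for (r in unique(rel$replicates)) {
    idx <- rel$replicates == r
    fl[, idx] <- rel$values[, idx, drop = FALSE] -
      rowMeans(rel$values[, idx, drop = FALSE])
  }
  attr(fl, "replicates") <- rel$replicates
  attr(fl, "time_steps") <- rel$time_steps
  fl
}

#' OTU-OTU linear correlation of fluctuation series
#'
#' Pearson correlation between the demeaned fluctuation series of every OTU
#' pair. `"pooled"` (default) computes one correlation over the
#' concatenation of all replicate blocks; `"per_replicate"` computes a
#' correlation per replicate and combines them by Fisher-z averaging.
#' Zero-variance OTUs get correlation 0 against everything (with a warning)
#' rather than NaN.
#'
#' @param fluctuations matrix from [fluctuation_series()].
#' @param pooling `"pooled"` or `"per_replicate"`.
#' @return object of class `correlation_result`: list with symmetric matrix
#'   `r` (unit diagonal), `method = "pearson_fluctuation"`, `pooling`, and
#'   slots `p_perm` / `p_lognormal` filled by the null-model functions.
#' @export
correlation_matrix <- function(fluctuations, pooling = c("pooled", "per_replicate")) {
  pooling <- match.arg(pooling)
  reps <- attr(fluctuations, "replicates")
  n <- nrow(fluctuations)
  flat <- function(block) {
    suppressWarnings(r <- stats::cor(t(block)))
    r
  }
  if (pooling == "pooled") {
    r <- flat(fluctuations)
  } else {
    zs <- array(NA_real_, dim = c(n, n, length(unique(reps))))
    for (k in seq_along(unique(reps))) {
      rr <- flat(fluctuations[, reps == unique(reps)[k], drop = FALSE])
      rr <- pmin(pmax(rr, -0.9999999), 0.9999999)
      zs[, , k] <- atanh(rr)
    }
    r <- tanh(apply(zs, c(1, 2), mean, na.rm = TRUE))
  }
  if (anyNA(r)) {
    warning("zero-variance OTU(s): their correlations are set to 0")
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  r <- (r + t(r)) / 2
  dimnames(r) <- list(rownames(fluctuations), rownames(fluctuations))
  structure(list(r = r, method = "pearson_fluctuation", pooling = pooling,
                 p_perm = NULL, p_lognormal = NULL),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result (%s, %s): %d x %d\n",
              x$method, x$pooling %||% "pooled", nrow(x$r), ncol(x$r)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one permuted copy of the fluctuation matrix: time order shuffled
# independently per OTU within each replicate block
permute_fluctuations <- function(fl, reps) {
  out <- fl
  for (r in unique(reps)) {
    idx <- which(reps == r)
    for (i in seq_len(nrow(fl)))
      out[i, idx] <- fl[i, idx[sample.int(length(idx))]]
  }
  out
}

#' Permutation-null p-values for OTU-OTU correlations
#'
#' Two-sided permutation test: time indices are permuted independently per
#' OTU within each replicate (destroying temporal alignment while keeping
#' every marginal), the correlation matrix is recomputed each round, and
#' `p = (1 + #\{|r_perm| >= |r_obs|\}) / (1 + n_permutations)` — so p is
#' never below `1 / (n_permutations + 1)`.
#'
#' @param fluctuations matrix from [fluctuation_series()].
#' @param r_observed observed correlation matrix (or a `correlation_result`).
#' @param n_permutations at least 99 (default 999).
#' @param seed integer seed.
#' @param pooling passed to [correlation_matrix()] for the permuted rounds.
#' @return symmetric matrix of p-values in `(0, 1]` (diagonal 1).
#' @export
permutation_pvalues <- function(fluctuations, r_observed, n_permutations = 999,
                                seed = 1L, pooling = "pooled") {
  if (inherits(r_observed, "correlation_result")) r_observed <- r_observed$r
  if (n_permutations < 99) stop("use at least 99 permutations")
  reps <- attr(fluctuations, "replicates")
  set.seed(seed)
  hits <- matrix(0, nrow(fluctuations), nrow(fluctuations))
  abs_obs <- abs(r_observed)
  for (b in seq_len(n_permutations)) {
    fp <- permute_fluctuations(fluctuations, reps)
    attr(fp, "replicates") <- reps
    rp <- suppressWarnings(correlation_matrix(fp, pooling = pooling)$r)
    hits <- hits + (abs(rp) >= abs_obs - 1e-12)
  }
  p <- (1 + hits) / (1 + n_permutations)
  diag(p) <- 1
  p <- pmin((p + t(p)) / 2, 1)
  dimnames(p) <- dimnames(r_observed)
  p
}

#' Lognormal-simulation null p-values for OTU-OTU correlations
#'
#' Parametric null: for each OTU, `(mu, sigma)` of `ln(count + 1)` are fitted
#' across all samples; `n_simulations` independent lognormal count tables of
#' identical shape are simulated, the full correlation statistic (closure,
#' demeaning, Pearson) is recomputed each round, and two-sided p-values use
#' the add-one convention. OTUs with fewer than 2 positive counts borrow the
#' global median sigma.
#'
#' @param table the [experiment_table()] the observed correlations came from.
#' @param r_observed observed correlation matrix (or `correlation_result`).
#' @param n_simulations at least 100 (default 10000).
#' @param seed integer seed.
#' @param pooling passed to [correlation_matrix()].
#' @return symmetric matrix of p-values in `(0, 1]` (diagonal 1).
#' @export
lognormal_null_pvalues <- function(table, r_observed, n_simulations = 10000,
                                   seed = 1L, pooling = "pooled") {
  stopifnot(inherits(table, "experiment_table"))
  if (inherits(r_observed, "correlation_result")) r_observed <- r_observed$r
  if (n_simulations < 100) stop("use at least 100 simulations")
  lc <- log(table$counts + 1)
  mu <- rowMeans(lc)
  sigma <- apply(lc, 1, stats::sd)
  few <- rowSums(table$counts > 0) < 2L
  global <- stats::median(sigma[!few & sigma > 0])
  if (any(few | sigma == 0)) {
    warning("OTU(s) with < 2 positive counts or zero spread: using global median sigma")
    sigma[few | sigma == 0] <- global
  }
  n <- nrow(lc); m <- ncol(lc)
  set.seed(seed)
  hits <- matrix(0, n, n)
  abs_obs <- abs(r_observed)
  for (b in seq_len(n_simulations)) {
    sim <- matrix(exp(stats::rnorm(n * m, mean = mu, sd = sigma)), n, m) - 1
    sim <- pmax(round(sim), 0)
    tot <- colSums(sim)
    rel <- sweep(sim, 2, ifelse(tot > 0, tot, 1), "/")
    rel[, tot == 0] <- 1 / n       # guard: an all-zero simulated sample
    # demean within replicate blocks, as for the observed statistic
    for (r in unique(table$replicates)) {
      idx <- table$replicates == r
      rel[, idx] <- rel[, idx, drop = FALSE] - rowMeans(rel[, idx, drop = FALSE])
    }
    attr(rel, "replicates") <- table$replicates
    rp <- suppressWarnings(correlation_matrix(rel, pooling = pooling)$r)
    hits <- hits + (abs(rp) >= abs_obs - 1e-12)
  }
  p <- (1 + hits) / (1 + n_simulations)
  diag(p) <- 1
  p <- pmin((p + t(p)) / 2, 1)
  dimnames(p) <- dimnames(r_observed)
  p
}

#' Attach both null models to a correlation result
#'
#' Convenience wrapper that fills the `p_perm` and `p_lognormal` slots of a
#' [correlation_matrix()] result.
#'
#' @param result a `correlation_result`.
#' @param fluctuations matrix from [fluctuation_series()].
#' @param table the source [experiment_table()].
#' @param n_permutations,n_simulations sizes of the two nulls.
#' @param seed integer seed (the two nulls use `seed` and `seed + 1`).
#' @return the `correlation_result` with p-value matrices filled.
#' @export
correlation_significance <- function(result, fluctuations, table,
                                     n_permutations = 999,
                                     n_simulations = 10000, seed = 1L) {
  result$p_perm <- permutation_pvalues(fluctuations, result$r,
                                       n_permutations = n_permutations,
                                       seed = seed, pooling = result$pooling)
  result$p_lognormal <- lognormal_null_pvalues(table, result$r,
                                               n_simulations = n_simulations,
                                               seed = seed + 1L,
                                               pooling = result$pooling)
  result
}
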