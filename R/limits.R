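#' Regression dataset for discrete Lotka-Volterra inference
#'
#' Under the stochastic dLV model, the log change of taxon i over a
#' transition of length `dt` days is
#' `ln x_i(t + dt) - ln x_i(t) = dt * sum_j c_ij (x_j(t) - <x_j>) + ln eta_i`.
#' This builds the per-transition responses `y_i = (ln x_i(t+dt) - ln x_i(t)) / dt`
#' (so coefficients are per-day rates regardless of the uneven transfer
#' intervals) and predictors `x_j(t) - <x_j>`, with the equilibrium `<x_j>`
#' estimated as the per-OTU median relative abundance over all samples
#' (robust to the transient early steps; the mean is available). Transitions
#' never span replicate boundaries. Zeros are replaced by a pseudo relative
#' abundance (default: half the smallest nonzero value in the table) before
#' logging.
#'
#' @param rel a `relative_abundance_table` (see [to_relative_abundance()]).
#' @param pseudo_rel replacement for zero relative abundances (default half
#'   the smallest positive value).
#' @param equilibrium `"median"` (default) or `"mean"` per-OTU equilibrium.
#' @return object of class `regression_dataset`: list with response matrix
#'   `Y` (transitions x OTUs), predictor matrix `X` (transitions x OTUs,
#'   centered at the equilibria), `dt`, `replicate` per transition,
#'   `equilibria`, `otu_ids`.
#' @export
build_regression_dataset <- function(rel, pseudo_rel = NULL,
                                     equilibrium = c("median", "mean")) {
  stopifnot(inherits(rel, "relative_abundance_table"))
  equilibrium <- match.arg(equilibrium)
  x <- rel$values
  all_zero <- rowSums(x) == 0
  if (any(all_zero)) {
    warning("OTU(s) with zero abundance everywhere excluded: ",
            paste(rel$otu_ids[all_zero], collapse = ", "))
    x <- x[!all_zero, , drop = FALSE]
  }
  ids <- rel$otu_ids[!all_zero]
  if (is.null(pseudo_rel)) pseudo_rel <- min(x[x > 0]) / 2
  xz <- x
  xz[xz == 0] <- pseudo_rel
  eq <- if (equilibrium == "median") apply(x, 1, stats::median) else rowMeans(x)

  reps <- unique(rel$replicates)
  Y_list <- list(); X_list <- list(); dt_all <- numeric(); rep_all <- integer()
  for (r in reps) {
    idx <- which(rel$replicates == r)
    idx <- idx[order(rel$time_steps[idx])]
    steps <- rel$time_steps[idx]
    if (length(idx) < 2L) next
    for (k in seq_len(length(idx) - 1L)) {
      # transitions only between consecutive sampled steps
      if (steps[k + 1L] != steps[k] + 1L) next
      dt <- rel$step_intervals_days[steps[k]]
      Y_list[[length(Y_list) + 1L]] <-
        (log(xz[, idx[k + 1L]]) - log(xz[, idx[k]])) / dt
      X_list[[length(X_list) + 1L]] <- x[, idx[k]] - eq
      dt_all <- c(dt_all, dt)
      rep_all <- c(rep_all, r)
    }
  }
  if (!length(Y_list)) stop("no usable transitions (need >= 2 time steps per replicate)")
  Y <- do.call(rbind, Y_list)
  X <- do.call(rbind, X_list)
  colnames(Y) <- colnames(X) <- ids
  if (any(!is.finite(Y)) || any(!is.finite(X)))
    stop("non-finite entries in the regression dataset after zero handling")
  structure(
    list(Y = Y, X = X, dt = dt_all, replicate = rep_all,
         equilibria = stats::setNames(eq, ids), otu_ids = ids,
         pseudo_rel = pseudo_rel),
    class = "regression_dataset"
  )
}

# least-squares fit (no intercept: the dLV response has none) with ridge
# fallback when the design is singular; returns coefficients
ls_coef <- function(X, y) {
  qr_fit <- qr(X)
  if (qr_fit$rank < ncol(X)) {
    G <- crossprod(X)
    lambda <- 1e-6 * sum(diag(G))
    if (lambda <= 0) lambda <- 1e-12
    return(as.numeric(solve(G + diag(lambda, ncol(X)), crossprod(X, y))))
  }
  as.numeric(qr.coef(qr_fit, y))
}

# forward stepwise selection for one target OTU on a fixed train/test split;
# returns list(active, coef) where coef is the train least-squares fit of
# the final active set
stepwise_select <- function(X, y, target, train, improvement_threshold) {
  test <- setdiff(seq_len(nrow(X)), train)
  n_pred <- ncol(X)
  active <- target
  coef_a <- ls_coef(X[train, active, drop = FALSE], y[train])
  mse <- function(active, coef_a) {
    pred <- X[test, active, drop = FALSE] %*% coef_a
    mean((y[test] - pred)^2)
  }
  err <- mse(active, coef_a)
  repeat {
    candidates <- setdiff(seq_len(n_pred), active)
    if (!length(candidates) || err == 0) break
    best_err <- Inf; best_j <- NA_integer_; best_coef <- NULL
    for (j in candidates) {
      trial <- c(active, j)
      cf <- ls_coef(X[train, trial, drop = FALSE], y[train])
      e <- mse(trial, cf)
      if (e < best_err) { best_err <- e; best_j <- j; best_coef <- cf }
    }
    if (!is.finite(best_err)) break
    improvement <- (err - best_err) / err
    if (is.na(improvement) || improvement < improvement_threshold) break
    active <- c(active, best_j)
    coef_a <- best_coef
    err <- best_err
  }
  list(active = active, coef = coef_a, test_mse = err)
}

#' Infer the dLV interaction matrix by LIMITS
#'
#' Sparse inference of the directed interaction coefficients `c_ij`
#' (influence of taxon j on taxon i) by forward stepwise regression with
#' bootstrap aggregation. For each target OTU and each bag, the transitions
#' are split at random into train and test halves; starting from the
#' self-interaction alone, the predictor whose inclusion (least-squares
#' refit on the train half) most reduces the test mean-squared error is
#' added repeatedly, stopping when the best relative improvement falls below
#' `improvement_threshold`. The bag estimate is the train least-squares fit
#' of the final predictor set (unselected entries 0). Across bags, entries
#' are aggregated by the median (robust to the instabilities bagging is
#' meant to cure), the selection fraction is recorded as support, and
#' entries with support at or above `keep_fraction` are flagged significant.
#'
#' Because relative abundances determine the coefficients only up to an
#' overall multiplicative constant (the design matrix of compositional data
#' is singular in that direction), the aggregated matrix is rescaled so
#' the median `|c_ii|` equals 1; the scale factor is recorded.
#'
#' @param ds a [build_regression_dataset()] result.
#' @param improvement_threshold minimum relative test-error improvement to
#'   accept a predictor (default 0.01).
#' @param n_bags number of random train/test splits (default 100, >= 2).
#' @param keep_fraction support needed to call an entry significant
#'   (default 0.5).
#' @param seed integer seed.
#' @return object of class `interaction_matrix`: list with `c` (normalized
#'   coefficients), `support`, `significant`, `normalization` (the divisor
#'   applied), `otu_ids`, and the call parameters.
#' @export
limits_infer <- function(ds, improvement_threshold = 0.01, n_bags = 100,
                         keep_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(ds, "regression_dataset"))
  if (n_bags < 2) stop("n_bags must be >= 2")
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  n_obs <- nrow(ds$X)
  n <- ncol(ds$X)
  if (n_obs < 4L) stop("too few transitions for a train/test split")
  set.seed(seed)
  splits <- lapply(seq_len(n_bags), function(b)
    sample.int(n_obs, floor(n_obs / 2)))

  c_bags <- array(0, dim = c(n, n, n_bags))
  selected <- array(FALSE, dim = c(n, n, n_bags))
  for (i in seq_len(n)) {
    for (b in seq_len(n_bags)) {
      fit <- stepwise_select(ds$X, ds$Y[, i], target = i,
                             train = splits[[b]],
                             improvement_threshold = improvement_threshold)
      c_bags[i, fit$active, b] <- fit$coef
      selected[i, fit$active, b] <- TRUE
    }
  }
  cmat <- apply(c_bags, c(1, 2), stats::median)
  support <- apply(selected, c(1, 2), mean)
  significant <- support >= keep_fraction
  scale <- stats::median(abs(diag(cmat)))
  if (!is.finite(scale) || scale == 0) scale <- 1
  cmat <- cmat / scale
  dimnames(cmat) <- dimnames(support) <- dimnames(significant) <-
    list(ds$otu_ids, ds$otu_ids)
  structure(
    list(c = cmat, support = support, significant = significant,
         normalization = scale, otu_ids = ds$otu_ids,
         improvement_threshold = improvement_threshold, n_bags = n_bags,
         keep_fraction = keep_fraction, seed = seed),
    class = "interaction_matrix"
  )
}

#' @export
print.interaction_matrix <- function(x, ...) {
  n_sig <- sum(x$significant & row(x$significant) != col(x$significant))
  cat(sprintf("interaction_matrix: %d OTUs, %d significant off-diagonal entries (support >= %.2f over %d bags)\n",
              nrow(x$c), n_sig, x$keep_fraction, x$n_bags))
  invisible(x)
}

#' Significant positive interactions, strongest first
#'
#' Extracts the off-diagonal entries flagged significant with positive
#' coefficient, reported once per unordered OTU pair with both directed
#' strengths (`NA` when a direction is not significant-positive), sorted by
#' the largest directed `|c|` descending.
#'
#' @param m an [limits_infer()] result.
#' @return data.frame with columns `otu_i`, `otu_j`, `c_ij` (influence of j
#'   on i), `c_ji`, `support_ij`, `support_ji`, `strength` (max of the two
#'   `|c|`).
#' @export
significant_positive_interactions <- function(m) {
  stopifnot(inherits(m, "interaction_matrix"))
  sig <- m$significant & m$c > 0
  diag(sig) <- FALSE
  idx <- which(sig, arr.ind = TRUE)
  empty <- data.frame(otu_i = character(), otu_j = character(),
                      c_ij = numeric(), c_ji = numeric(),
                      support_ij = numeric(), support_ji = numeric(),
                      strength = numeric())
  if (!nrow(idx)) return(empty)
  key <- apply(idx, 1, function(k) paste(sort(k), collapse = "_"))
  rows <- lapply(unique(key), function(kk) {
    ij <- as.integer(strsplit(kk, "_")[[1]])
    a <- ij[1L]; b <- ij[2L]
    data.frame(
      otu_i = m$otu_ids[a], otu_j = m$otu_ids[b],
      c_ij = if (sig[a, b]) m$c[a, b] else NA_real_,
      c_ji = if (sig[b, a]) m$c[b, a] else NA_real_,
      support_ij = m$support[a, b], support_ji = m$support[b, a],
      strength = max(abs(m$c[a, b][sig[a, b]]), abs(m$c[b, a][sig[b, a]]), 0)
    )
  })
  out <- do.call(rbind, rows)
  out[order(-out$strength), , drop = FALSE]
}
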