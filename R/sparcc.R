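#' Basic SparCC-style compositional correlation estimator
#'
#' Correlation inference designed for compositional count data: pairwise
#' log-ratio variances `T_ij = Var(ln((n_i + pc) / (n_j + pc)))` over samples
#' are decomposed into per-OTU basis variances `w_i` under the sparse
#' approximation `T_ij ~ w_i + w_j - 2 r_ij sqrt(w_i w_j)` with the sum of
#' correlation terms neglected, giving the linear system
#' `(n - 2) w_i + sum_j w_j = t_i` with `t_i = sum_{j != i} T_ij`. The
#' correlation estimate is `r_ij = (w_i + w_j - T_ij) / (2 sqrt(w_i w_j))`,
#' clipped to `[-1, 1]`. Because strongly correlated pairs violate the
#' sparsity assumption, the strongest pair with `|r| > 0.1` is excluded from
#' the basis system and the solve repeated, `n_exclusion_iters` times.
#'
#' Ratios of counts equal ratios of relative abundances within a sample, so
#' the estimator is invariant to sequencing depth by construction.
#'
#' @param table an [experiment_table()] with at least 4 OTUs.
#' @param n_exclusion_iters iterations of strong-pair exclusion (default 10;
#'   0 gives the closed-form one-shot solution).
#' @param pseudocount added to every count before taking log ratios
#'   (default 0.5).
#' @param exclusion_threshold `|r|` above which a pair can be excluded from
#'   the basis estimate (default 0.1).
#' @return a `correlation_result` with `method = "sparcc_basic"`.
#' @export
sparcc_basic <- function(table, n_exclusion_iters = 10, pseudocount = 0.5,
                         exclusion_threshold = 0.1) {
  stopifnot(inherits(table, "experiment_table"))
  n <- nrow(table$counts)
  if (n < 4L) stop("the basis-variance system needs at least 4 OTUs")
  lx <- log(table$counts + pseudocount)
  # T_ij = Var(l_i - l_j) = V_ii + V_jj - 2 V_ij
  V <- stats::cov(t(lx))
  Tmat <- outer(diag(V), diag(V), "+") - 2 * V
  diag(Tmat) <- 0

  excluded <- matrix(FALSE, n, n)
  solve_basis <- function() {
    M <- matrix(1, n, n)
    M[excluded] <- 0
    diag(M) <- n - 1 - rowSums(excluded)
    t_i <- rowSums(Tmat * (!excluded)) # excluded pairs leave the sums
    as.numeric(solve(M, t_i))
  }
  corr_from <- function(w) {
    r <- (outer(w, w, "+") - Tmat) / (2 * sqrt(outer(w, w)))
    pmin(pmax(r, -1), 1)
  }

  w <- solve_basis()
  fallback <- any(w <= 0)
  if (!fallback) {
    r <- corr_from(w)
    iters <- 0L
    while (iters < n_exclusion_iters) {
      cand <- abs(r)
      cand[excluded | row(cand) >= col(cand)] <- 0
      if (max(cand) <= exclusion_threshold) break
      ij <- which(cand == max(cand), arr.ind = TRUE)[1L, ]
      excluded[ij[1L], ij[2L]] <- excluded[ij[2L], ij[1L]] <- TRUE
      w_new <- solve_basis()
      if (any(w_new <= 0)) { fallback <- TRUE; break }
      w <- w_new
      r <- corr_from(w)
      iters <- iters + 1L
    }
  }
  if (fallback) {
    warning("non-positive basis variance; falling back to Pearson on log counts")
    r <- suppressWarnings(stats::cor(t(lx)))
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  r <- (r + t(r)) / 2
  dimnames(r) <- list(table$otu_ids, table$otu_ids)
  structure(list(r = r, method = "sparcc_basic", pooling = "pooled",
                 p_perm = NULL, p_lognormal = NULL),
            class = "correlation_result")
}
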