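#' Convert a correlation matrix to distances
#'
#' Linear map `d = 1 - r`: full positive correlation maps to distance 0,
#' full negative correlation to distance 2, zero correlation to 1. The map
#' is order-reversing, so more positively correlated OTUs sit closer.
#'
#' @param r symmetric correlation matrix with entries in `[-1, 1]`.
#' @return symmetric distance matrix in `[0, 2]` with zero diagonal.
#' @export
correlation_to_distance <- function(r) {
  r <- as.matrix(r)
  if (max(abs(r)) > 1 + 1e-9) stop("correlations must lie in [-1, 1]")
  r <- pmin(pmax(r, -1), 1)
  d <- 1 - r
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Kruskal stress-1 of a configuration
#'
#' `stress = sqrt( sum_{i<j} (dhat_ij - theta_ij)^2 / sum_{i<j} dhat_ij^2 )`
#' where `dhat` are the Euclidean distances of the embedded points and
#' `theta` is the monotone (isotonic, pool-adjacent-violators) regression of
#' `dhat` on the rank order of the input dissimilarities. Ties in the input
#' dissimilarities are handled by the primary approach: tied inputs may map
#' to fitted values in any order (implemented by ordering ties by `dhat`).
#'
#' @param d input dissimilarity matrix (or `dist`).
#' @param coordinates configuration matrix, points in rows.
#' @return stress-1 value in `[0, 1]`.
#' @export
kruskal_stress <- function(d, coordinates) {
  dv <- as.numeric(stats::as.dist(d))
  dhat <- as.numeric(stats::dist(coordinates))
  stopifnot(length(dv) == length(dhat))
  ord <- order(dv, dhat)               # primary approach to ties
  fit <- stats::isoreg(dhat[ord])$yf   # PAVA on dhat in input-rank order
  sqrt(sum((dhat[ord] - fit)^2) / sum(dhat^2))
}

#' Non-metric multidimensional scaling with Kruskal stress-1
#'
#' Embeds OTUs in `n_dims` dimensions so that the rank order of the input
#' dissimilarities is preserved as well as possible, minimizing Kruskal
#' stress-1 (monotone regression with the primary approach to ties). The
#' optimisation is restarted from a classical (metric) MDS configuration
#' plus `n_restarts - 1` random configurations, and the best solution is
#' kept. NMDS solutions are defined only up to rotation, reflection and
#' translation, so the returned configuration is centered, rotated to its
#' principal axes, and sign-fixed (the largest-magnitude loading of each
#' axis is made positive) to be comparable across runs.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal (or `dist`).
#' @param n_dims embedding dimension (default 3, so correlated, uncorrelated
#'   and anticorrelated taxa are separable without 2D projection ambiguity).
#' @param n_restarts number of starting configurations (default 20).
#' @param max_iter iteration cap per restart (default 500).
#' @param tol relative stress-improvement tolerance (default 1e-7).
#' @param seed integer seed for the random restarts.
#' @return object of class `nmds_embedding`: list with `coordinates`
#'   (`n x n_dims`, centered and principal-axis aligned), `stress`
#'   (recomputed by [kruskal_stress()] on the returned coordinates),
#'   `n_restarts`, `best_restart_seed`, `converged`.
#' @export
nmds <- function(d, n_dims = 3, n_restarts = 20, max_iter = 500,
                 tol = 1e-7, seed = 1L) {
  dm <- as.matrix(d)
  if (nrow(dm) <= n_dims)
    stop("need more points than embedding dimensions")
  if (max(abs(dm - t(dm))) > 1e-8 || max(abs(diag(dm))) > 1e-8)
    stop("dissimilarity matrix must be symmetric with zero diagonal")
  dd <- stats::as.dist(dm)
  n <- nrow(dm)

  # metric start; fall back to jitter if the double-centered matrix degenerates
  set.seed(seed)
  metric0 <- tryCatch(
    suppressWarnings(stats::cmdscale(dd, k = n_dims)),
    error = function(e) NULL)
  if (is.null(metric0) || ncol(metric0) < n_dims) {
    extra <- matrix(stats::rnorm(n * n_dims, sd = 1e-4), n, n_dims)
    base <- if (is.null(metric0)) 0 else cbind(metric0,
              matrix(0, n, n_dims - ncol(metric0)))
    metric0 <- base + extra
  }

  best <- NULL
  best_seed <- NA_integer_
  restart_seeds <- sample.int(.Machine$integer.max - 1L, n_restarts)
  for (k in seq_len(n_restarts)) {
    set.seed(restart_seeds[k])
    init <- if (k == 1L) metric0 else matrix(stats::rnorm(n * n_dims), n, n_dims)
    fit <- tryCatch(
      vegan::monoMDS(dd, y = init, k = n_dims, model = "global",
                     maxit = max_iter, smin = tol, sfgrmin = tol,
                     sratmax = 1 - tol),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit
      best_seed <- restart_seeds[k]
    }
  }
  if (is.null(best)) stop("NMDS failed in every restart")
  converged <- isTRUE(best$icause != 1L)   # 1 = iteration cap hit
  if (!converged)
    warning("NMDS did not converge in any restart; returning the best configuration")

  xy <- scale(best$points, center = TRUE, scale = FALSE)
  sv <- svd(xy)
  xy <- sv$u %*% diag(sv$d, n_dims)    # principal-axis rotation
  for (j in seq_len(ncol(xy))) {       # sign convention per axis
    i_max <- which.max(abs(xy[, j]))
    if (xy[i_max, j] < 0) xy[, j] <- -xy[, j]
  }
  rownames(xy) <- rownames(dm)
  colnames(xy) <- paste0("dim", seq_len(n_dims))
  structure(
    list(coordinates = xy, stress = kruskal_stress(dm, xy),
         n_restarts = n_restarts, best_restart_seed = best_seed,
         converged = converged),
    class = "nmds_embedding"
  )
}

#' @export
print.nmds_embedding <- function(x, ...) {
  cat(sprintf("NMDS embedding: %d points in %dD, stress-1 = %.4f (%s)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              stress_label(x$stress)))
  invisible(x)
}

#' Verbal goodness-of-fit label for a stress value
#'
#' Kruskal's conventional benchmarks: 0.2 poor, 0.1 fair, 0.05 good,
#' 0.025 excellent. Values falling between two benchmarks are labelled
#' "between X and Y"; values at or above 0.2 are "poor", at or below 0.025
#' "excellent".
#'
#' @param stress stress-1 value in `[0, 1]`.
#' @return character label.
#' @export
stress_label <- function(stress) {
  stopifnot(stress >= 0, stress <= 1)
  if (stress >= 0.2) return("poor")
  if (stress == 0.1) return("fair")
  if (stress == 0.05) return("good")
  if (stress <= 0.025) return("excellent")
  if (stress > 0.1) return("between poor and fair")
  if (stress > 0.05) return("between fair and good")
  "between good and excellent"
}

#' Detect consortia as connected components of the significant-positive graph
#'
#' Builds a graph with an edge between two OTUs whenever their correlation
#' is positive (optionally above `min_r`) and significant at level `alpha`;
#' putative consortia are the connected components with at least 2 members.
#' Singletons stay unassigned. Groups are numbered in decreasing order of
#' summed member abundance (falling back to component size when no
#' abundances are given).
#'
#' @param r correlation matrix (or a `correlation_result`, whose permutation
#'   p-values are then used by default).
#' @param p matrix of p-values conformable with `r`.
#' @param alpha significance level for an edge (default 0.05).
#' @param min_r optional minimum correlation for an edge (default 0).
#' @param abundances optional per-OTU mean abundances used to order groups.
#' @return object of class `consortium_assignment`: list with `groups`
#'   (list of OTU-id vectors) and `membership` (named integer vector,
#'   `NA` for unassigned OTUs).
#' @export
detect_consortia <- function(r, p = NULL, alpha = 0.05, min_r = 0,
                             abundances = NULL) {
  if (inherits(r, "correlation_result")) {
    if (is.null(p)) p <- r$p_perm
    r <- r$r
  }
  if (is.null(p)) stop("p-value matrix required (run a null model first)")
  stopifnot(all(dim(r) == dim(p)))
  ids <- rownames(r) %||% paste0("OTU_", seq_len(nrow(r)))
  adj <- (r > min_r) & (p <= alpha)
  diag(adj) <- FALSE
  adj <- adj & t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(ids, comp$membership)
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  if (length(groups)) {
    weight <- if (is.null(abundances)) {
      vapply(groups, length, 1)
    } else {
      ab <- abundances
      if (is.null(names(ab))) names(ab) <- ids
      vapply(groups, function(g) sum(ab[g]), 1)
    }
    groups <- groups[order(-weight)]
    names(groups) <- seq_along(groups)
  }
  membership <- rep(NA_integer_, length(ids))
  names(membership) <- ids
  for (k in seq_along(groups)) membership[groups[[k]]] <- k
  structure(list(groups = groups, membership = membership),
            class = "consortium_assignment")
}

#' @export
print.consortium_assignment <- function(x, ...) {
  cat(sprintf("%d consortium/consortia:\n", length(x$groups)))
  for (k in seq_along(x$groups))
    cat(sprintf("  %s: %s\n", names(x$groups)[k],
                paste(x$groups[[k]], collapse = ", ")))
  invisible(x)
}
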