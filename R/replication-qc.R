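#' Taylor-law fluctuation scaling across replicates
#'
#' Validates the randomness of replicate cultures at one time step: for each
#' OTU, the mean and standard deviation of its abundance across replicates
#' are computed, and the slope of the ordinary least-squares fit of
#' log10(sd) on log10(mean) is the fluctuation-scaling exponent. Replicates
#' behaving as independent Poisson draws give slope 1/2; slope 1 indicates
#' purely multiplicative (lognormal-like) variation.
#'
#' OTUs with zero mean or zero standard deviation across replicates are
#' excluded (their logarithms are undefined); at least 3 usable OTUs are
#' required.
#'
#' @param table an [experiment_table()] (at least 2 replicates).
#' @param time_step 1-based time step at which replicates are compared
#'   (default 1, the first sampled step).
#' @param on fit on raw `"counts"` (default) or on within-sample relative
#'   `"frequency"`.
#' @return object of class `taylor_fit`: list with `slope`, `intercept`,
#'   `slope_stderr`, `n_otus_used`, `log_base` (10), and the per-OTU
#'   `log_mean`/`log_sd` points.
#' @export
taylor_law_fit <- function(table, time_step = 1L, on = c("counts", "frequency")) {
  stopifnot(inherits(table, "experiment_table"))
  on <- match.arg(on)
  sel <- table$time_steps == time_step
  if (!any(sel)) stop("no samples at time step ", time_step)
  x <- table$counts[, sel, drop = FALSE]
  if (ncol(x) < 2L) stop("need at least 2 replicates at time step ", time_step)
  if (on == "frequency") x <- sweep(x, 2, colSums(x), "/")
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  usable <- mu > 0 & sdv > 0
  if (sum(usable) < 3L)
    stop(sprintf("only %d OTU(s) with positive mean and sd across replicates; need >= 3",
                 sum(usable)))
  lm_fit <- stats::lm(log10(sdv[usable]) ~ log10(mu[usable]))
  coefs <- summary(lm_fit)$coefficients
  structure(
    list(slope = unname(coefs[2L, 1L]), intercept = unname(coefs[1L, 1L]),
         slope_stderr = unname(coefs[2L, 2L]), n_otus_used = sum(usable),
         log_base = 10,
         log_mean = log10(mu[usable]), log_sd = log10(sdv[usable])),
    class = "taylor_fit"
  )
}

#' @export
print.taylor_fit <- function(x, ...) {
  cat(sprintf("Taylor-law fit: slope %.3f +/- %.3f (%d OTUs, log10)\n",
              x$slope, x$slope_stderr, x$n_otus_used))
  invisible(x)
}

#' Per-sample diversity profile
#'
#' Shannon entropy (natural log), Simpson index and species richness for
#' every sample. Simpson defaults to the Gini-Simpson form `1 - sum(p^2)`;
#' the dominance (`sum(p^2)`) and inverse (`1 / sum(p^2)`) forms are
#' available. Richness counts OTUs with a positive count.
#'
#' @param table an [experiment_table()].
#' @param simpson_form `"gini"` (default), `"dominance"`, or `"inverse"`.
#' @return data.frame with columns `replicate`, `time_step`, `shannon`,
#'   `simpson`, `richness`.
#' @export
diversity_profile <- function(table, simpson_form = c("gini", "dominance", "inverse")) {
  stopifnot(inherits(table, "experiment_table"))
  simpson_form <- match.arg(simpson_form)
  m <- t(table$counts)             # vegan wants samples in rows
  if (any(rowSums(m) == 0)) stop("all-zero sample: diversity undefined")
  shannon <- vegan::diversity(m, index = "shannon")   # nats
  d2 <- rowSums(sweep(m, 1, rowSums(m), "/")^2)       # sum p_i^2
  simpson <- switch(simpson_form,
                    gini = 1 - d2, dominance = d2, inverse = 1 / d2)
  data.frame(replicate = table$replicates, time_step = table$time_steps,
             shannon = unname(shannon), simpson = unname(simpson),
             richness = colSums(table$counts > 0), row.names = NULL)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(u, v) = 1 - 2 * sum(min(u_i, v_i)) / (sum(u) + sum(v))` on counts:
#' 0 for identical samples, 1 for samples with disjoint OTU support.
#'
#' @param table an [experiment_table()] with at least 2 samples.
#' @return symmetric sample-by-sample matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(table) {
  stopifnot(inherits(table, "experiment_table"))
  if (ncol(table$counts) < 2L) stop("need at least 2 samples")
  as.matrix(vegan::vegdist(t(table$counts), method = "bray"))
}

#' ANOSIM permutation test on a dissimilarity matrix
#'
#' Analysis of similarities: ranks all pairwise dissimilarities and compares
#' mean between-group to mean within-group ranks,
#' `R = (mean_between - mean_within) / (M / 2)` with `M = n(n-1)/2`.
#' Significance by label permutation with the add-one convention
#' `p = (1 + #\{R_perm >= R_obs\}) / (1 + n_permutations)`, so p can never
#' drop below `1 / (n_permutations + 1)`.
#'
#' @param dist square dissimilarity matrix or `dist` object.
#' @param grouping group label per sample (each group needs >= 2 members).
#' @param n_permutations number of permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @return list with `R`, `p_value`, `n_permutations`.
#' @export
anosim_test <- function(dist, grouping, n_permutations = 999, seed = NULL) {
  d <- stats::as.dist(dist)
  grouping <- as.factor(grouping)
  if (nlevels(grouping) < 2L) stop("need at least 2 groups")
  if (any(table(grouping) < 2L)) stop("every group needs at least 2 members")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::anosim(d, grouping, permutations = n_permutations)
  list(R = unname(fit$statistic), p_value = unname(fit$signif),
       n_permutations = n_permutations)
}
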