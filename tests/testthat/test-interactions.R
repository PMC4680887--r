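# regression dataset built directly from a known design (no closure), for
# testing the stepwise/bagging machinery against exact ground truth
make_direct_dataset <- function(cmat, n_obs = 160, seed = 1, noise_sd = 0.005) {
  set.seed(seed)
  n <- nrow(cmat)
  X <- matrix(rnorm(n_obs * n, sd = 0.05), n_obs, n)
  Y <- X %*% t(cmat) + matrix(rnorm(n_obs * n, sd = noise_sd), n_obs, n)
  ids <- paste0("OTU_", seq_len(n))
  colnames(X) <- colnames(Y) <- ids
  structure(list(Y = Y, X = X, dt = rep(1, n_obs),
                 replicate = rep(1L, n_obs),
                 equilibria = stats::setNames(rep(1 / n, n), ids),
                 otu_ids = ids, pseudo_rel = 1e-6),
            class = "regression_dataset")
}

test_that("the regression dataset lays out one response per transition", {
  cfg <- simulation_config(6, seed = 5, sequencing_depth = 1e4)
  rel <- to_relative_abundance(simulate_experiment(cfg)$table)
  ds <- build_regression_dataset(rel)
  expect_equal(nrow(ds$X), 80L)            # (9 - 1) x 10 replicates
  expect_equal(ncol(ds$X), 6L)
  expect_equal(sort(unique(ds$dt)), c(2, 3, 4))
  # transitions never span replicate boundaries
  expect_equal(as.vector(table(ds$replicate)), rep(8L, 10))
  expect_true(all(is.finite(ds$X)) && all(is.finite(ds$Y)))
})

test_that("constant series produce zero responses", {
  rel <- rel_table(matrix(c(0.4, 0.6), 2, 6), replicates = rep(1:2, each = 3),
                   time_steps = rep(1:3, 2), step_intervals_days = c(2, 3))
  ds <- build_regression_dataset(rel)
  expect_true(all(ds$Y == 0))
})

test_that("responses are per-day rates", {
  vals <- cbind(c(0.3, 0.7), c(0.6, 0.4))
  rel_a <- rel_table(vals, replicates = c(1, 1), time_steps = c(1, 2),
                     step_intervals_days = 1)
  rel_b <- rel_table(vals, replicates = c(1, 1), time_steps = c(1, 2),
                     step_intervals_days = 4)
  ya <- build_regression_dataset(rel_a)$Y
  yb <- build_regression_dataset(rel_b)$Y
  expect_equal(ya, 4 * yb)
})

test_that("noiseless closure residuals are shared across taxa", {
  # under compositional closure the only residual of the true-coefficient
  # fit is the per-transition renormalization term, identical for every OTU
  cfg <- cycle5_config(seed = 9, noise_sigma = 0, sequencing_depth = 1e7)
  sim <- simulate_experiment(cfg)
  lat <- sim$truth$latent_series            # exact states, no count noise
  tt <- sim$table$time_steps; rr <- sim$table$replicates
  cmat <- cfg$interaction_matrix; eq <- cfg$equilibrium_abundances
  for (r in 1:3) {
    idx <- which(rr == r)
    for (k in 1:8) {
      dt <- cfg$step_intervals_days[k]
      x0 <- lat[, idx[k]]; x1 <- lat[, idx[k + 1]]
      resid <- (log(x1) - log(x0)) / dt - as.numeric(cmat %*% (x0 - eq))
      expect_lt(diff(range(resid)), 1e-9)   # constant across OTUs
    }
  }
})

test_that("all-zero OTUs are excluded with a warning", {
  vals <- rbind(c(0.5, 0.6, 0.4, 0.5), c(0.5, 0.4, 0.6, 0.5), c(0, 0, 0, 0))
  tab <- experiment_table(round(vals * 1e4),
                          otu_ids = c("A", "B", "C"),
                          replicates = rep(1:2, each = 2),
                          time_steps = rep(1:2, 2))
  rel <- to_relative_abundance(tab)
  expect_warning(ds <- build_regression_dataset(rel), "excluded.*C")
  expect_equal(ds$otu_ids, c("A", "B"))
})

test_that("stepwise bagging recovers a known full-rank system exactly", {
  cmat <- matrix(0, 4, 4); diag(cmat) <- c(-1, -0.8, -1.2, -1)
  cmat[1, 3] <- 0.6; cmat[2, 4] <- -0.5
  ds <- make_direct_dataset(cmat, seed = 3)
  # planted predictors cut test error by ~97%, noise-level ones by a few
  # percent; a 5% threshold separates the two regimes cleanly
  m <- limits_infer(ds, improvement_threshold = 0.05, n_bags = 20, seed = 3)
  truth_n <- cmat / stats::median(abs(diag(cmat)))
  expect_lt(max(abs(m$c - truth_n)), 0.05)
  sig <- m$significant; diag(sig) <- FALSE
  expect_setequal(which(sig), which(cmat != 0 & row(cmat) != col(cmat)))
})

test_that("an infinite improvement threshold keeps only self-interactions", {
  ds <- make_direct_dataset(matrix(c(-1, 0.5, 0.5, -1), 2, 2), noise_sd = 0.01)
  m <- limits_infer(ds, improvement_threshold = Inf, n_bags = 5, seed = 1)
  off <- m$support; diag(off) <- 0
  expect_true(all(off == 0))
  expect_true(all(diag(m$support) == 1))
})

test_that("rescaling responses leaves selection unchanged and scales raw fits", {
  cmat <- matrix(0, 3, 3); diag(cmat) <- -1; cmat[1, 2] <- 0.7
  ds <- make_direct_dataset(cmat, seed = 4, noise_sd = 0.002)
  m1 <- limits_infer(ds, n_bags = 20, seed = 9)
  ds2 <- ds; ds2$Y <- ds$Y * 3
  m2 <- limits_infer(ds2, n_bags = 20, seed = 9)
  expect_identical(m1$support, m2$support)
  expect_equal(m2$normalization, 3 * m1$normalization, tolerance = 1e-9)
  expect_equal(m2$c, m1$c, tolerance = 1e-9)     # normalized scale-free
})

test_that("inference is deterministic under a fixed seed", {
  sim <- simulate_experiment(cycle5_config(seed = 2))
  ds <- build_regression_dataset(to_relative_abundance(sim$table))
  m1 <- limits_infer(ds, n_bags = 10, seed = 5)
  m2 <- limits_infer(ds, n_bags = 10, seed = 5)
  expect_identical(m1$c, m2$c)
  expect_identical(m1$support, m2$support)
})

test_that("planted cycle interactions are recovered with correct signs", {
  cmat <- cycle5_matrix()
  planted <- which(cmat > 0 & row(cmat) != col(cmat))
  hits <- vapply(1:12, function(s) {
    sim <- simulate_experiment(cycle5_config(seed = 100 + s))
    ds <- build_regression_dataset(to_relative_abundance(sim$table))
    m <- limits_infer(ds, n_bags = 50, seed = s)
    all(m$significant[planted] & m$c[planted] > 0)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("false-positive interactions stay calibrated without true coupling", {
  fp <- vapply(1:50, function(s) {
    cfg <- simulation_config(5, interaction_matrix = -diag(5),
                             equilibrium_abundances = rep(0.2, 5),
                             noise_sigma = 0.05, sequencing_depth = 1e5,
                             seed = s)
    sim <- simulate_experiment(cfg)
    ds <- build_regression_dataset(to_relative_abundance(sim$table))
    m <- limits_infer(ds, n_bags = 50, seed = s + 7)
    sig <- m$significant; diag(sig) <- FALSE
    sum(sig) / 20
  }, 1)
  expect_lte(mean(fp), 0.10)
})

test_that("positive interaction listing excludes the diagonal and sorts by strength", {
  ids <- paste0("OTU_", 1:3)
  m <- structure(list(
    c = matrix(c(-1, 0.2, 0, 0.9, -1, 0, 0, 0.4, -1), 3, 3,
               dimnames = list(ids, ids)),
    support = matrix(0.8, 3, 3, dimnames = list(ids, ids)),
    significant = matrix(TRUE, 3, 3, dimnames = list(ids, ids)),
    normalization = 1, otu_ids = ids, improvement_threshold = 0.01,
    n_bags = 10, keep_fraction = 0.5, seed = 1), class = "interaction_matrix")
  pos <- significant_positive_interactions(m)
  expect_false(any(pos$otu_i == pos$otu_j))
  expect_equal(pos$strength, sort(pos$strength, decreasing = TRUE))
  # the symmetric 1-2 pair is reported once with both directions
  expect_equal(nrow(pos), 2L)
  expect_equal(pos$strength[1], 0.9)

  m$significant[] <- FALSE
  expect_equal(nrow(significant_positive_interactions(m)), 0L)
})
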