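test_that("taylor slope is exact on collinear log points", {
  # three OTUs with sd proportional to mean: slope exactly 1
  counts <- rbind(c(1, 3), c(2, 6), c(4, 12))
  tab <- experiment_table(counts, replicates = c(1, 2), time_steps = c(1, 1))
  fit <- taylor_law_fit(tab, time_step = 1)
  expect_equal(fit$slope, 1)
  expect_equal(fit$n_otus_used, 3L)
  expect_equal(fit$log_base, 10)
})

test_that("degenerate replicate structure is rejected", {
  # all replicate values equal: every sd is zero, nothing to fit
  counts <- matrix(rep(c(5, 7, 9), 4), 3, 4)
  tab <- experiment_table(counts, replicates = 1:4, time_steps = rep(1, 4))
  expect_error(taylor_law_fit(tab, 1), ">= 3")
  expect_error(taylor_law_fit(small_table(), time_step = 99), "no samples")
})

test_that("poisson replicates scale with slope one half", {
  slopes <- vapply(1:30, function(s) {
    set.seed(s)
    lam <- 10^seq(0, 4, length.out = 26)
    counts <- sapply(1:10, function(r) rpois(26, lam))
    tab <- experiment_table(counts, replicates = 1:10, time_steps = rep(1, 10))
    taylor_law_fit(tab, 1)$slope
  }, 1)
  expect_lt(abs(mean(slopes) - 0.5), 0.05)
})

test_that("taylor slope is invariant to rescaling all counts at a step", {
  set.seed(8)
  counts <- matrix(rpois(26 * 10, 10^runif(260, 0.5, 3)), 26, 10)
  counts[1, colSums(counts) == 0] <- 1
  tab <- experiment_table(counts, replicates = 1:10, time_steps = rep(1, 10))
  tab10 <- tab; tab10$counts <- tab$counts * 10
  f1 <- taylor_law_fit(tab, 1); f10 <- taylor_law_fit(tab10, 1)
  expect_equal(f10$slope, f1$slope, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f10$intercept, f1$intercept)))
})

test_that("diversity indices match their closed forms", {
  tab <- experiment_table(matrix(c(1, 1, 1, 1), 4, 1),
                          replicates = 1, time_steps = 1)
  d <- diversity_profile(tab)
  expect_equal(d$shannon, log(4))
  expect_equal(d$simpson, 0.75)
  expect_equal(d$richness, 4L)

  tab1 <- experiment_table(matrix(c(5, 0, 0), 3, 1),
                           replicates = 1, time_steps = 1)
  d1 <- diversity_profile(tab1)
  expect_equal(d1$shannon, 0)
  expect_equal(d1$simpson, 0)
  expect_equal(d1$richness, 1L)

  expect_equal(diversity_profile(tab1, simpson_form = "dominance")$simpson, 1)
  expect_equal(diversity_profile(tab1, simpson_form = "inverse")$simpson, 1)

  # maximum-entropy bound on random samples
  set.seed(5)
  counts <- matrix(rpois(50, 5), 10, 5); counts[1, ] <- counts[1, ] + 1
  tabr <- experiment_table(counts, replicates = rep(1, 5), time_steps = 1:5,
                           step_intervals_days = rep(1, 4))
  dr <- diversity_profile(tabr)
  expect_true(all(dr$shannon <= log(dr$richness) + 1e-12))
})

test_that("bray-curtis matches the shared-abundance formula", {
  u <- c(6, 0); v <- c(2, 2)
  tab <- experiment_table(cbind(u, v), replicates = c(1, 2),
                          time_steps = c(1, 1))
  bc <- bray_curtis_matrix(tab)
  expect_equal(bc[1, 2], 1 - 2 * 2 / 10)   # hand value 0.6
  expect_equal(diag(bc), c(r1_t1 = 0, r2_t1 = 0))

  # identical samples at 0, disjoint supports at 1
  tab2 <- experiment_table(cbind(c(3, 1, 0), c(3, 1, 0), c(0, 0, 7)),
                           replicates = 1:3, time_steps = rep(1, 3))
  bc2 <- bray_curtis_matrix(tab2)
  expect_equal(bc2[1, 2], 0)
  expect_equal(bc2[1, 3], 1)

  # independent re-implementation of the formula on random counts
  set.seed(9)
  counts <- matrix(rpois(40, 8), 5, 8); counts[1, ] <- counts[1, ] + 1
  tabr <- experiment_table(counts, replicates = rep(1:2, each = 4),
                           time_steps = rep(1:4, 2),
                           step_intervals_days = rep(1, 3))
  bcr <- bray_curtis_matrix(tabr)
  manual <- function(a, b) 1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(bcr[i, j], manual(counts[, i], counts[, j]))
})

test_that("anosim separates disjoint groups and respects the p-value floor", {
  # two groups with disjoint OTU support: maximal separation
  counts <- cbind(c(9, 1, 0, 0), c(8, 2, 0, 0), c(7, 3, 0, 0),
                  c(0, 0, 9, 1), c(0, 0, 8, 2), c(0, 0, 7, 3))
  tab <- experiment_table(counts, replicates = 1:6, time_steps = rep(1, 6))
  bc <- bray_curtis_matrix(tab)
  res <- anosim_test(bc, rep(c("a", "b"), each = 3),
                     n_permutations = 199, seed = 1)
  expect_equal(res$R, 1)
  expect_gte(res$p_value, 1 / 200)

  expect_error(anosim_test(bc, c("a", rep("b", 5))), "at least 2 members")
  expect_error(anosim_test(bc, rep("a", 6)), "at least 2 groups")
})
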