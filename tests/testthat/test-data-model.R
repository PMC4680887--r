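test_that("reading a keyed OTU table recovers the sample design", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_small_tsv(f)
  tab <- read_experiment_table(f)
  expect_s3_class(tab, "experiment_table")
  expect_equal(dim(tab), c(3L, 4L))
  expect_equal(sort(unique(tab$replicates)), c(1L, 2L))
  expect_equal(max(tab$time_steps), 2L)
  # samples sorted by (replicate, time step)
  expect_equal(colnames(tab$counts), c("r1_t1", "r1_t2", "r2_t1", "r2_t2"))
})

test_that("malformed tables are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tr1_t1\tr1_t1", "A\t1\t2", "B\t3\t4"), f)
  expect_error(read_experiment_table(f), "duplicate sample key")

  writeLines(c("otu_id\tr1_t1\tr1_t2", "A\t1\t-2", "B\t3\t4"), f)
  expect_error(read_experiment_table(f), "negative count.*'A'.*'r1_t2'")

  writeLines(c("otu_id\tr1_t1\tr1_t2", "A\t1\tx", "B\t3\t4"), f)
  expect_error(read_experiment_table(f), "'A'.*'r1_t2'")

  writeLines(c("otu_id\tsampleX", "A\t1"), f)
  expect_error(read_experiment_table(f), "not matching pattern")

  expect_error(read_experiment_table(file.path(tempdir(), "nope.tsv")),
               "not found")
})

test_that("write then read round-trips an experiment table", {
  tab <- small_table()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_experiment_table(tab, f)
  back <- read_experiment_table(f, step_intervals_days = tab$step_intervals_days)
  expect_identical(back$counts, tab$counts)
  expect_identical(back$otu_ids, tab$otu_ids)
  expect_identical(back$replicates, tab$replicates)
  expect_identical(back$time_steps, tab$time_steps)
  expect_identical(back$step_intervals_days, tab$step_intervals_days)
})

test_that("relative abundances close each sample to one", {
  tab <- experiment_table(matrix(c(2, 2), 2, 1), replicates = 1, time_steps = 1)
  expect_equal(unname(to_relative_abundance(tab)$values[, 1]), c(0.5, 0.5))

  tab2 <- experiment_table(matrix(c(0, 4, 1, 1), 2, 2),
                           replicates = c(1, 1), time_steps = c(1, 2))
  rel2 <- to_relative_abundance(tab2, pseudocount = 1)
  expect_equal(unname(rel2$values[, 1]), c(1 / 6, 5 / 6))

  set.seed(4)
  counts <- matrix(rpois(60, 20), 6, 10)
  counts[1, 1] <- counts[1, 1] + 1  # ensure positive column sums
  tab3 <- experiment_table(counts, replicates = rep(1:2, each = 5),
                           time_steps = rep(1:5, 2))
  rel3 <- to_relative_abundance(tab3)
  expect_true(all(abs(colSums(rel3$values) - 1) < 1e-9))
})

test_that("relative abundance is scale-invariant and rejects empty samples", {
  tab <- small_table()
  rel <- to_relative_abundance(tab)
  scaled <- tab
  scaled$counts[, 2] <- scaled$counts[, 2] * 17
  rel_scaled <- to_relative_abundance(scaled)
  expect_equal(rel_scaled$values, rel$values)

  counts <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_error(experiment_table(counts, replicates = c(1, 1),
                                time_steps = c(1, 2)),
               "no positive count")
})

test_that("abundant-OTU selection ranks, thresholds and breaks ties by id", {
  counts <- rbind(c(6, 4), c(5, 4), c(4, 4), c(1, 1), c(1, 0))
  tab <- experiment_table(counts, otu_ids = paste0("O", 1:5),
                          replicates = c(1, 1), time_steps = 1:2,
                          step_intervals_days = 1)
  top3 <- select_abundant_otus(tab, "top_k", k = 3)
  expect_equal(top3$otu_ids, c("O1", "O2", "O3"))

  # strict ">" keeps only totals above the threshold
  tab2 <- experiment_table(matrix(c(150, 100, 99), 3, 1),
                           replicates = 1, time_steps = 1)
  kept <- select_abundant_otus(tab2, "min_total_count", min_count = 100)
  expect_equal(rowSums(kept$counts), c(OTU_1 = 150))

  # identity when k equals the pool, warning when it exceeds it
  expect_equal(select_abundant_otus(tab, "top_k", k = 5)$otu_ids, tab$otu_ids)
  expect_warning(all5 <- select_abundant_otus(tab, "top_k", k = 9), "exceeds")
  expect_equal(all5$otu_ids, tab$otu_ids)

  # ranking by mean relative abundance is exposed as an alternative basis
  expect_equal(
    select_abundant_otus(tab, "top_k", k = 2,
                         rank_by = "mean_relative_abundance")$otu_ids,
    c("O1", "O2"))

  # tie at rank k broken lexicographically by OTU id
  tie <- experiment_table(matrix(c(5, 5, 5), 3, 1),
                          otu_ids = c("Ob", "Oa", "Oc"),
                          replicates = 1, time_steps = 1)
  expect_equal(select_abundant_otus(tie, "top_k", k = 2)$otu_ids, c("Ob", "Oa"))
})

test_that("taxonomy tables parse ranks with explicit missing markers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tclass\torder\tfamily\tgenus\tspecies",
               "OTU_1\tGammaproteobacteria\tPseudomonadales\tPseudomonadaceae\tPseudomonas\t-",
               "OTU_2\tBetaproteobacteria\tBurkholderiales\t\t\t"), f)
  tax <- read_taxonomy_table(f)
  expect_equal(names(tax), c("otu_id", "class", "order", "family", "genus", "species"))
  expect_identical(tax$species, c(NA_character_, NA_character_))
  expect_equal(tax$genus[1], "Pseudomonas")
})
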