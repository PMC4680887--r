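# shared fixtures, all generated in code

# tiny 3-OTU table over 2 replicates x 2 steps
small_table <- function() {
  counts <- matrix(c(10, 5, 1,
                     8, 6, 2,
                     12, 4, 0,
                     9, 7, 1), nrow = 3,
                   dimnames = list(c("OTU_a", "OTU_b", "OTU_c"), NULL))
  experiment_table(counts, replicates = c(1, 1, 2, 2), time_steps = c(1, 2, 1, 2),
                   step_intervals_days = 2)
}

write_small_tsv <- function(path, header = c("r1_t1", "r1_t2", "r2_t1", "r2_t2")) {
  tab <- small_table()
  df <- data.frame(otu_id = tab$otu_ids, tab$counts)
  names(df)[-1] <- header
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# 5-OTU interaction cycle, columns balanced against equal equilibria so the
# planted matrix is the identifiable representative of its equivalence class
cycle5_matrix <- function() {
  cmat <- -diag(5)
  for (j in 1:5) cmat[j %% 5 + 1, j] <- 1
  cmat
}

cycle5_config <- function(seed, noise_sigma = 0.05, sequencing_depth = 1e5) {
  simulation_config(5, interaction_matrix = cycle5_matrix(),
                    equilibrium_abundances = rep(0.2, 5),
                    noise_sigma = noise_sigma,
                    sequencing_depth = sequencing_depth, seed = seed)
}

# three consortia of four members interleaved across the abundance ladder;
# equal equilibria keep every group a minority share of the community
planted12_groups <- function() list(c(1, 4, 7, 10), c(2, 5, 8, 11), c(3, 6, 9, 12))

planted12_config <- function(seed, within_strength = 1.5) {
  planted_consortia_config(12, planted12_groups(),
                           within_strength = within_strength,
                           equilibrium_abundances = rep(1 / 12, 12),
                           noise_sigma = 0.2, sequencing_depth = 1e5,
                           seed = seed)
}

# white-noise fluctuation matrix (independent series), demeaned per replicate
white_noise_fluct <- function(n_otus, n_replicates = 10, n_steps = 9, seed = 1) {
  set.seed(seed)
  reps <- rep(seq_len(n_replicates), each = n_steps)
  fl <- matrix(stats::rnorm(n_otus * length(reps)), n_otus)
  for (r in seq_len(n_replicates))
    fl[, reps == r] <- fl[, reps == r] - rowMeans(fl[, reps == r, drop = FALSE])
  attr(fl, "replicates") <- reps
  fl
}

# relative-abundance table built directly from a value matrix
rel_table <- function(values, replicates, time_steps, step_intervals_days = NULL) {
  tab <- experiment_table(round(values * 1e6), replicates = replicates,
                          time_steps = time_steps,
                          step_intervals_days = step_intervals_days)
  to_relative_abundance(tab)
}

expect_symmetric <- function(m, tol = 1e-12) {
  expect_lt(max(abs(m - t(m))), tol)
}
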