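#' Experiment table: OTU counts across replicated culture time series
#'
#' An `experiment_table` holds a non-negative integer count matrix (OTUs in
#' rows, samples in columns) together with the sample design: each sample is
#' keyed by a (replicate, time step) pair, and consecutive time steps are
#' separated by a known number of days. It is the sole input of the analysis
#' pipeline; all downstream modules consume it or its relative-abundance
#' counterpart.
#'
#' @param counts numeric matrix, OTUs x samples, non-negative counts.
#' @param otu_ids character vector of OTU identifiers (rownames used if `NULL`).
#' @param replicates integer vector, 1-based replicate index per sample column.
#' @param time_steps integer vector, 1-based time-step index per sample column.
#' @param step_intervals_days positive numeric vector of length
#'   `n_steps - 1`: days elapsed between consecutive sub-culturing steps.
#'   Defaults to 1 day per transition when not supplied.
#'
#' @return An object of class `experiment_table`: a list with elements
#'   `counts`, `otu_ids`, `replicates`, `time_steps`, `step_intervals_days`.
#'   Samples are stored sorted by (replicate, time step).
#' @export
experiment_table <- function(counts, otu_ids = NULL, replicates, time_steps,
                             step_intervals_days = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(otu_ids)) otu_ids <- rownames(counts)
  if (is.null(otu_ids)) otu_ids <- paste0("OTU_", seq_len(nrow(counts)))
  otu_ids <- as.character(otu_ids)
  if (length(otu_ids) != nrow(counts))
    stop("otu_ids length must match the number of count rows")
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU ids: ", paste(otu_ids[duplicated(otu_ids)], collapse = ", "))
  replicates <- as.integer(replicates)
  time_steps <- as.integer(time_steps)
  if (length(replicates) != ncol(counts) || length(time_steps) != ncol(counts))
    stop("replicates and time_steps must have one entry per sample column")
  if (any(replicates < 1L) || any(time_steps < 1L))
    stop("replicate and time-step indices are 1-based and must be >= 1")
  key <- paste0("r", replicates, "_t", time_steps)
  if (anyDuplicated(key))
    stop("duplicate sample key(s): ", paste(unique(key[duplicated(key)]), collapse = ", "))
  if (any(!is.finite(counts)))
    stop("counts contain non-finite values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at OTU '%s', sample '%s'",
                 otu_ids[bad[1L]], key[bad[2L]]))
  }
  if (any(colSums(counts) == 0))
    stop("sample(s) with no positive count: ",
         paste(key[colSums(counts) == 0], collapse = ", "))

  ord <- order(replicates, time_steps)
  counts <- counts[, ord, drop = FALSE]
  replicates <- replicates[ord]
  time_steps <- time_steps[ord]
  n_steps <- max(time_steps)
  if (is.null(step_intervals_days)) {
    step_intervals_days <- rep(1, max(n_steps - 1L, 0L))
  }
  step_intervals_days <- as.numeric(step_intervals_days)
  if (length(step_intervals_days) != n_steps - 1L)
    stop(sprintf("step_intervals_days must have length n_steps - 1 = %d, got %d",
                 n_steps - 1L, length(step_intervals_days)))
  if (any(step_intervals_days <= 0))
    stop("step intervals must be positive")
  dimnames(counts) <- list(otu_ids, paste0("r", replicates, "_t", time_steps))
  structure(
    list(counts = counts, otu_ids = otu_ids, replicates = replicates,
         time_steps = time_steps, step_intervals_days = step_intervals_days),
    class = "experiment_table"
  )
}

#' @export
print.experiment_table <- function(x, ...) {
  cat(sprintf("experiment_table: %d OTUs x %d samples (%d replicates x %d time steps)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$replicates)), max(x$time_steps)))
  cat("step intervals (days):", paste(x$step_intervals_days, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.experiment_table <- function(x) dim(x$counts)

#' Sub-culturing intervals of the replicated resin-culture design
#'
#' The experimental design emulated by the simulator uses nine sub-culturing
#' steps with uneven spacing: 4 days for the first two transitions, then 3,
#' then four 2-day transfers with a 3-day transition before the final 2-day
#' one (24 days in total).
#'
#' @return numeric vector of length 8 (days per transition).
#' @export
default_step_intervals <- function() c(4, 4, 3, 2, 2, 2, 3, 2)

#' Read an OTU count table keyed by replicate and time step
#'
#' Reads a tab-separated file whose first column holds OTU identifiers and
#' whose remaining column headers encode the sample design, by default as
#' `r<replicate>_t<time>`. A custom regular expression with two capture
#' groups (replicate, then time step) accommodates other header dialects.
#'
#' @param path path to the TSV file.
#' @param sample_key_pattern regular expression with exactly two integer
#'   capture groups: replicate then time step.
#' @param step_intervals_days optional per-transition day intervals (see
#'   [experiment_table()]).
#' @return an [experiment_table()].
#' @export
read_experiment_table <- function(path, sample_key_pattern = "^r(\\d+)_t(\\d+)$",
                                  step_intervals_days = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected an OTU id column plus at least one sample column")
  keys <- colnames(df)[-1L]
  if (anyDuplicated(keys))
    stop("duplicate sample key in header: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  m <- regmatches(keys, regexec(sample_key_pattern, keys))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("sample header(s) not matching pattern '", sample_key_pattern, "': ",
         paste(keys[bad], collapse = ", "))
  replicates <- vapply(m, function(g) as.integer(g[2L]), 1L)
  time_steps <- vapply(m, function(g) as.integer(g[3L]), 1L)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(counts)) {
    suppress <- suppressWarnings(num <- apply(df[, -1L, drop = FALSE], 2, as.numeric))
    bad <- which(is.na(num) & !is.na(as.matrix(df[, -1L, drop = FALSE])), arr.ind = TRUE)
    if (length(bad))
      stop(sprintf("non-numeric count at OTU '%s', sample '%s'",
                   df[[1L]][bad[1L, 1L]], keys[bad[1L, 2L]]))
    counts <- num
  }
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)
    stop(sprintf("missing/non-numeric count at OTU '%s', sample '%s'",
                 df[[1L]][bad[1L, 1L]], keys[bad[1L, 2L]]))
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)
    stop(sprintf("negative count at OTU '%s', sample '%s'",
                 df[[1L]][bad[1L, 1L]], keys[bad[1L, 2L]]))
  }
  experiment_table(counts, otu_ids = df[[1L]], replicates = replicates,
                   time_steps = time_steps,
                   step_intervals_days = step_intervals_days)
}

#' Write an experiment table to TSV
#'
#' Inverse of [read_experiment_table()]: first column `otu_id`, one column per
#' sample headed `r<replicate>_t<time>`. Round-trips losslessly for integer
#' counts (intervals must be carried separately).
#'
#' @param table an [experiment_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_experiment_table <- function(table, path) {
  stopifnot(inherits(table, "experiment_table"))
  df <- data.frame(otu_id = table$otu_ids, table$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table (lineage per OTU)
#'
#' Tab-separated file with columns `otu_id`, `class`, `order`, `family`,
#' `genus`, `species` (at most five ranks, fixed order; unknown ranks as
#' empty strings or `-`/`NA`, stored as `NA`).
#'
#' @param path path to the TSV file.
#' @return data.frame with `otu_id` plus the five rank columns.
#' @export
read_taxonomy_table <- function(path) {
  ranks <- c("class", "order", "family", "genus", "species")
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (names(df)[1L] != "otu_id") names(df)[1L] <- "otu_id"
  missing_ranks <- setdiff(ranks, names(df))
  for (r in missing_ranks) df[[r]] <- NA_character_
  df <- df[, c("otu_id", ranks)]
  for (r in ranks) {
    v <- trimws(as.character(df[[r]]))
    v[v %in% c("", "-", "NA")] <- NA_character_
    df[[r]] <- v
  }
  if (anyDuplicated(df$otu_id)) stop("duplicate otu_id in taxonomy table")
  df
}

#' Convert counts to relative abundances
#'
#' Per-sample closure: each column is divided by its (pseudocount-augmented)
#' total so relative abundances sum to one. With the default pseudocount of 0
#' the transform is pure normalization and scale-invariant; modules that log
#' the data apply their own zero handling.
#'
#' @param table an [experiment_table()].
#' @param pseudocount non-negative value added to every count before closure.
#' @return object of class `relative_abundance_table` with the same structure
#'   as the input, `values` in `[0, 1]` and columns summing to 1.
#' @export
to_relative_abundance <- function(table, pseudocount = 0) {
  stopifnot(inherits(table, "experiment_table"), pseudocount >= 0)
  x <- table$counts + pseudocount
  tot <- colSums(x)
  if (any(tot == 0))
    stop("all-zero sample(s) with pseudocount 0: ",
         paste(colnames(table$counts)[tot == 0], collapse = ", "))
  structure(
    list(values = sweep(x, 2, tot, "/"), otu_ids = table$otu_ids,
         replicates = table$replicates, time_steps = table$time_steps,
         step_intervals_days = table$step_intervals_days),
    class = "relative_abundance_table"
  )
}

#' @export
print.relative_abundance_table <- function(x, ...) {
  cat(sprintf("relative_abundance_table: %d OTUs x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Restrict an experiment table to its abundant OTUs
#'
#' The analysis pool is the abundant fraction of the community: either the
#' top `k` OTUs by a ranking statistic (default: total count over all
#' samples; alternatively mean relative abundance), or all OTUs with total
#' count strictly greater than a threshold. Original OTU order is preserved;
#' ties at rank `k` are broken lexicographically by OTU id.
#'
#' @param table an [experiment_table()].
#' @param mode `"top_k"` or `"min_total_count"`.
#' @param k number of OTUs to keep (`mode = "top_k"`; default 26, the usual
#'   size of the abundant pool in a replicated resin-culture experiment).
#' @param min_count threshold for `mode = "min_total_count"`; OTUs with total
#'   count strictly greater than `min_count` are kept.
#' @param rank_by ranking statistic for `top_k`: `"total_count"` or
#'   `"mean_relative_abundance"`.
#' @return an [experiment_table()] restricted to the qualifying OTUs.
#' @export
select_abundant_otus <- function(table, mode = c("top_k", "min_total_count"),
                                 k = 26, min_count = 100,
                                 rank_by = c("total_count", "mean_relative_abundance")) {
  stopifnot(inherits(table, "experiment_table"))
  mode <- match.arg(mode)
  rank_by <- match.arg(rank_by)
  totals <- rowSums(table$counts)
  if (mode == "top_k") {
    if (k > nrow(table$counts)) {
      warning(sprintf("k = %d exceeds the %d available OTUs; returning all",
                      k, nrow(table$counts)))
      k <- nrow(table$counts)
    }
    stat <- if (rank_by == "total_count") totals else {
      rel <- sweep(table$counts, 2, colSums(table$counts), "/")
      rowMeans(rel)
    }
    # rank by statistic descending, ties broken by OTU id (lexicographic)
    ord <- order(-stat, table$otu_ids)
    keep_ids <- table$otu_ids[ord[seq_len(k)]]
    keep <- table$otu_ids %in% keep_ids
  } else {
    keep <- totals > min_count   # strict ">"
  }
  experiment_table(table$counts[keep, , drop = FALSE],
                   otu_ids = table$otu_ids[keep],
                   replicates = table$replicates, time_steps = table$time_steps,
                   step_intervals_days = table$step_intervals_days)
}

#' Write a labelled numeric matrix as TSV
#'
#' Helper used for every derived matrix (correlations, p-values, distances,
#' coordinates, interaction coefficients): row labels in the first column,
#' column labels in the header.
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @param row_label header for the label column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, row_label = "id") {
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1L] <- row_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
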