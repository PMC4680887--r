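#' Configuration of a full consortium-mapping run
#'
#' One object holds every stage's parameters so a run is fully reproducible:
#' the same config (and seed) always produces the same numeric outputs. The
#' config is serialized as JSON next to the outputs.
#'
#' @param input path to an OTU count TSV, or a [simulation_config()] to
#'   generate the input in silico. Exactly one must be given.
#' @param step_intervals_days per-transition day intervals for file input
#'   (default [default_step_intervals()] for 9-step designs).
#' @param top_k abundant-OTU pool size (default 26; `NA` keeps all OTUs).
#' @param taylor_time_step time step at which replicate randomness is
#'   validated (default 1).
#' @param method correlation method, `"pearson"` or `"sparcc"`.
#' @param pooling `"pooled"` or `"per_replicate"` fluctuation pooling.
#' @param n_permutations permutation-null size (default 999).
#' @param n_lognormal_sims lognormal-null size (default 10000; set 0 to skip).
#' @param alpha edge significance level for consortium detection (default
#'   0.05).
#' @param fdr apply Benjamini-Hochberg correction to the p-values before
#'   thresholding (default `FALSE`, mirroring raw-alpha practice; `TRUE`
#'   recommended for large OTU pools).
#' @param n_dims,n_restarts NMDS dimension (3) and restarts (20).
#' @param improvement_threshold,n_bags,keep_fraction LIMITS parameters.
#' @param plot_format `"png"`, `"svg"`, `"html"`, or `NA` to skip plotting.
#' @param seed one integer seed governing all stochastic stages.
#' @param outdir output directory (created if missing).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, step_intervals_days = NULL, top_k = 26,
                            taylor_time_step = 1L,
                            method = c("pearson", "sparcc"),
                            pooling = c("pooled", "per_replicate"),
                            n_permutations = 999, n_lognormal_sims = 10000,
                            alpha = 0.05, fdr = FALSE,
                            n_dims = 3, n_restarts = 20,
                            improvement_threshold = 0.01, n_bags = 100,
                            keep_fraction = 0.5,
                            plot_format = "svg", seed = 1L, outdir) {
  method <- match.arg(method)
  pooling <- match.arg(pooling)
  if (!inherits(input, "simulation_config") && !is.character(input))
    stop("input must be a file path or a simulation_config")
  structure(
    list(input = input, step_intervals_days = step_intervals_days,
         top_k = top_k, taylor_time_step = as.integer(taylor_time_step),
         method = method, pooling = pooling,
         n_permutations = n_permutations, n_lognormal_sims = n_lognormal_sims,
         alpha = alpha, fdr = fdr, n_dims = n_dims, n_restarts = n_restarts,
         improvement_threshold = improvement_threshold, n_bags = n_bags,
         keep_fraction = keep_fraction, plot_format = plot_format,
         seed = as.integer(seed), outdir = outdir),
    class = "pipeline_config"
  )
}

serialize_config <- function(config) {
  x <- unclass(config)
  if (inherits(x$input, "simulation_config")) {
    x$input <- unclass(x$input)
    x$input$interaction_matrix <- unname(as.matrix(x$input$interaction_matrix))
  }
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

stage <- function(name, code) {
  t0 <- Sys.time()
  message(sprintf("[%s] starting", name))
  out <- tryCatch(code, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full consortium-mapping pipeline
#'
#' Executes, in order: input (read or simulate) and abundant-OTU selection;
#' replicate QC (Taylor-law fit, per-sample diversity, Bray-Curtis + ANOSIM
#' by time step); correlation with permutation and lognormal nulls; distance
#' conversion, 3D NMDS, and consortium detection; LIMITS interaction
#' inference; and the consortium-map figure. All stage tables are written as
#' TSV, the configuration as JSON, and the headline numbers as
#' `report.json`.
#'
#' @param config a [pipeline_config()].
#' @return the report, invisibly (a list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeLines(as.character(serialize_config(config)),
             file.path(outdir, "config.json"))

  table <- stage("input", {
    if (inherits(config$input, "simulation_config")) {
      sim <- simulate_experiment(config$input)
      write_matrix_tsv(sim$truth$config$interaction_matrix *
                         1,  # ground truth for provenance
                       file.path(outdir, "true_interactions.tsv"),
                       row_label = "otu")
      write_experiment_table(sim$table, file.path(outdir, "simulated_counts.tsv"))
      sim$table
    } else {
      if (!file.exists(config$input)) stop("input file not found: ", config$input)
      read_experiment_table(config$input,
                            step_intervals_days = config$step_intervals_days)
    }
  })
  if (!is.na(config$top_k) && config$top_k < nrow(table$counts))
    table <- select_abundant_otus(table, mode = "top_k", k = config$top_k)

  qc <- stage("qc", {
    taylor <- taylor_law_fit(table, time_step = config$taylor_time_step)
    div <- diversity_profile(table)
    utils::write.table(div, file.path(outdir, "diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    bc <- bray_curtis_matrix(table)
    write_matrix_tsv(bc, file.path(outdir, "bray_curtis.tsv"), "sample")
    anosim_time <- anosim_test(bc, table$time_steps,
                               n_permutations = config$n_permutations,
                               seed = config$seed)
    anosim_rep <- anosim_test(bc, table$replicates,
                              n_permutations = config$n_permutations,
                              seed = config$seed)
    list(taylor = taylor, anosim_time = anosim_time, anosim_rep = anosim_rep)
  })

  rel <- to_relative_abundance(table)
  corr <- stage("correlate", {
    fl <- fluctuation_series(rel)
    res <- if (config$method == "pearson") {
      correlation_matrix(fl, pooling = config$pooling)
    } else {
      sparcc_basic(table)
    }
    res$p_perm <- permutation_pvalues(fl, res$r,
                                      n_permutations = config$n_permutations,
                                      seed = config$seed,
                                      pooling = config$pooling)
    if (config$n_lognormal_sims > 0)
      res$p_lognormal <- lognormal_null_pvalues(table, res$r,
                                                n_simulations = config$n_lognormal_sims,
                                                seed = config$seed + 1L,
                                                pooling = config$pooling)
    write_matrix_tsv(res$r, file.path(outdir, "r.tsv"), "otu_id")
    write_matrix_tsv(res$p_perm, file.path(outdir, "p_perm.tsv"), "otu_id")
    if (!is.null(res$p_lognormal))
      write_matrix_tsv(res$p_lognormal, file.path(outdir, "p_lognormal.tsv"), "otu_id")
    res
  })

  emb <- stage("embed", {
    d <- correlation_to_distance(corr$r)
    write_matrix_tsv(d, file.path(outdir, "distance.tsv"), "otu_id")
    e <- nmds(d, n_dims = config$n_dims, n_restarts = config$n_restarts,
              seed = config$seed)
    coords <- data.frame(otu_id = rownames(e$coordinates), e$coordinates,
                         check.names = FALSE)
    utils::write.table(coords, file.path(outdir, "coordinates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    e
  })

  mean_ab <- rowMeans(rel$values)
  consortia <- stage("consortia", {
    p <- corr$p_perm
    if (config$fdr) {
      pv <- p[upper.tri(p)]
      p[upper.tri(p)] <- stats::p.adjust(pv, method = "BH")
      p[lower.tri(p)] <- t(p)[lower.tri(p)]
    }
    a <- detect_consortia(corr$r, p, alpha = config$alpha,
                          abundances = mean_ab)
    utils::write.table(
      data.frame(otu_id = names(a$membership), group = unname(a$membership)),
      file.path(outdir, "consortia.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    a
  })

  inter <- stage("interactions", {
    ds <- build_regression_dataset(rel)
    m <- limits_infer(ds, improvement_threshold = config$improvement_threshold,
                      n_bags = config$n_bags,
                      keep_fraction = config$keep_fraction,
                      seed = config$seed)
    write_matrix_tsv(m$c, file.path(outdir, "interaction_matrix.tsv"), "otu_id")
    write_matrix_tsv(m$support, file.path(outdir, "interaction_support.tsv"), "otu_id")
    pos <- significant_positive_interactions(m)
    utils::write.table(pos, file.path(outdir, "interactions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(matrix = m, positive = pos)
  })

  if (!is.na(config$plot_format)) stage("plot", {
    spec <- build_plot_spec(emb, consortia, mean_ab, inter$positive)
    render(spec, file.path(outdir, paste0("consortium_map.", config$plot_format)),
           format = config$plot_format)
  })

  report <- list(
    n_otus = nrow(table$counts),
    n_samples = ncol(table$counts),
    taylor_slope = qc$taylor$slope,
    taylor_slope_stderr = qc$taylor$slope_stderr,
    anosim_time_R = qc$anosim_time$R,
    anosim_time_p = qc$anosim_time$p_value,
    anosim_replicate_R = qc$anosim_rep$R,
    anosim_replicate_p = qc$anosim_rep$p_value,
    stress = emb$stress,
    stress_label = stress_label(emb$stress),
    n_consortia = length(consortia$groups),
    consortia = consortia$groups,
    n_significant_positive_interactions = nrow(inter$positive),
    significant_positive_interactions = inter$positive
  )
  writeLines(as.character(jsonlite::toJSON(report, auto_unbox = TRUE,
                                           digits = NA, null = "null",
                                           dataframe = "rows")),
             file.path(outdir, "report.json"))
  invisible(report)
}
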