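#' Configuration of a simulated replicated sub-culturing experiment
#'
#' Bundles the community model and study design used by
#' [simulate_experiment()]: a stochastic discrete Lotka-Volterra (dLV) system
#' on relative abundances with interaction matrix `c_ij` (influence of taxon
#' j on taxon i, per day), equilibrium abundances set by the carrying
#' capacity of the environment, lognormal multiplicative process noise, and
#' count-sampling observation noise at a fixed sequencing depth.
#'
#' @param n_otus number of taxa.
#' @param interaction_matrix `n_otus x n_otus` signed matrix `c_ij`
#'   (per-day rates); diagonal must be `<= 0` (self-limitation).
#' @param equilibrium_abundances simplex vector of carrying-capacity
#'   abundances (sums to 1).
#' @param n_replicates number of independent replicate cultures (default 10).
#' @param n_steps number of sub-culturing steps sampled (default 9).
#' @param step_intervals_days days between consecutive steps (default the
#'   uneven 4,4,3,2,2,2,3,2-day design of [default_step_intervals()]).
#' @param noise_sigma standard deviation of the log of the multiplicative
#'   lognormal noise applied per taxon per transition (default 0.2).
#' @param sequencing_depth reads drawn per sample (default 1e5).
#' @param initial_dirichlet_concentration the initial composition of each
#'   replicate is drawn from Dirichlet(concentration * equilibrium); larger
#'   values give tighter replicate-to-replicate spread (default 50).
#' @param observation_model `"multinomial"` (fixed depth, default) or
#'   `"poisson"` (each OTU's count independently Poisson at rate
#'   `depth * x_i`, the model under which replicate fluctuation scaling has
#'   Taylor slope 1/2).
#' @param seed integer seed; one root RNG drives the whole simulation, with
#'   per-replicate sub-streams derived deterministically from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_otus,
                              interaction_matrix = NULL,
                              equilibrium_abundances = NULL,
                              n_replicates = 10, n_steps = 9,
                              step_intervals_days = NULL,
                              noise_sigma = 0.2,
                              sequencing_depth = 1e5,
                              initial_dirichlet_concentration = 50,
                              observation_model = c("multinomial", "poisson"),
                              seed = 1L) {
  observation_model <- match.arg(observation_model)
  if (is.null(interaction_matrix))
    interaction_matrix <- -diag(n_otus)
  interaction_matrix <- as.matrix(interaction_matrix)
  if (!all(dim(interaction_matrix) == c(n_otus, n_otus)))
    stop("interaction_matrix must be n_otus x n_otus")
  if (any(diag(interaction_matrix) > 0))
    stop("diagonal of the interaction matrix must be <= 0 (self-limitation)")
  if (is.null(equilibrium_abundances))
    equilibrium_abundances <- log_spaced_equilibrium(n_otus)
  equilibrium_abundances <- as.numeric(equilibrium_abundances)
  if (length(equilibrium_abundances) != n_otus)
    stop("equilibrium_abundances must have length n_otus")
  if (any(equilibrium_abundances <= 0) ||
      abs(sum(equilibrium_abundances) - 1) > 1e-9)
    stop("equilibrium_abundances must be positive and sum to 1")
  if (is.null(step_intervals_days)) {
    step_intervals_days <- if (n_steps == 9) default_step_intervals()
                           else rep(1, n_steps - 1L)
  }
  if (length(step_intervals_days) != n_steps - 1L || any(step_intervals_days <= 0))
    stop("step_intervals_days must be positive and of length n_steps - 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (sequencing_depth < 1) stop("sequencing_depth must be >= 1")
  structure(
    list(n_otus = n_otus, interaction_matrix = interaction_matrix,
         equilibrium_abundances = equilibrium_abundances,
         n_replicates = as.integer(n_replicates), n_steps = as.integer(n_steps),
         step_intervals_days = as.numeric(step_intervals_days),
         noise_sigma = noise_sigma, sequencing_depth = sequencing_depth,
         initial_dirichlet_concentration = initial_dirichlet_concentration,
         observation_model = observation_model, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# equilibria log-spaced over one decade, normalised to the simplex
log_spaced_equilibrium <- function(n_otus) {
  if (n_otus == 1L) return(1)
  e <- 10^seq(0, -1, length.out = n_otus)
  e / sum(e)
}

#' One stochastic discrete Lotka-Volterra update on the simplex
#'
#' Propagates a composition over `dt` days:
#' `x_i' proportional to eta_i * x_i * exp(dt * sum_j c_ij (x_j - e_j))`
#' with `ln eta_i ~ Normal(0, noise_sigma^2)`, followed by renormalization to
#' the simplex (the model is stated in relative abundances, so compositional
#' closure is applied every step). The equilibrium `e` is a fixed point of
#' the noiseless map, as is any `x` when `c = 0`.
#'
#' Uses the caller's RNG state; seed management belongs to
#' [simulate_experiment()].
#'
#' @param x simplex vector (current relative abundances).
#' @param interaction matrix `c_ij` of per-day interaction rates.
#' @param equilibrium simplex vector of carrying-capacity abundances.
#' @param dt transition length in days (> 0).
#' @param noise_sigma sd of the lognormal noise on the log scale (>= 0).
#' @return the next composition (sums to 1).
#' @export
dlv_step <- function(x, interaction, equilibrium, dt, noise_sigma = 0) {
  stopifnot(dt > 0, noise_sigma >= 0)
  n <- length(x)
  growth <- dt * as.numeric(interaction %*% (x - equilibrium))
  log_eta <- if (noise_sigma > 0) stats::rnorm(n, 0, noise_sigma) else numeric(n)
  u <- x * exp(growth + log_eta)
  if (any(!is.finite(u)))
    stop("non-finite abundance in dLV step (|c| * dt too large); ",
         "rescale the interaction matrix or shorten the interval")
  s <- sum(u)
  if (s <= 0 || !is.finite(s))
    stop("degenerate dLV step: total abundance is not positive")
  u / s
}

#' Simulate a replicated sub-culturing experiment
#'
#' For each replicate, draws an initial composition from
#' Dirichlet(concentration * equilibrium), propagates it through
#' `n_steps - 1` dLV transitions with the per-transition day intervals, and
#' converts every latent composition to counts (multinomial at fixed depth,
#' or independent Poisson). Deterministic under a fixed seed; per-replicate
#' RNG sub-streams are derived from the root seed so results do not depend
#' on evaluation order.
#'
#' @param config a [simulation_config()].
#' @return list with elements `table` (an [experiment_table()] of counts) and
#'   `truth` (class `ground_truth`: the config plus the latent relative
#'   abundances before count sampling).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_otus
  withr_seed <- function(seed, code) {
    old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    code()
  }
  rep_seeds <- withr_seed(config$seed, function()
    sample.int(.Machine$integer.max - 1L, config$n_replicates))

  otu_ids <- paste0("OTU_", seq_len(n))
  n_samples <- config$n_replicates * config$n_steps
  counts <- matrix(0, n, n_samples)
  latent <- matrix(0, n, n_samples)
  replicates <- integer(n_samples)
  time_steps <- integer(n_samples)

  col <- 0L
  for (r in seq_len(config$n_replicates)) {
    block <- withr_seed(rep_seeds[r], function() {
      alpha <- config$initial_dirichlet_concentration * config$equilibrium_abundances
      g <- stats::rgamma(n, shape = alpha, rate = 1)
      if (sum(g) == 0) g <- config$equilibrium_abundances
      x <- g / sum(g)
      lat <- matrix(0, n, config$n_steps)
      cnt <- matrix(0, n, config$n_steps)
      for (t in seq_len(config$n_steps)) {
        if (t > 1L)
          x <- dlv_step(x, config$interaction_matrix,
                        config$equilibrium_abundances,
                        dt = config$step_intervals_days[t - 1L],
                        noise_sigma = config$noise_sigma)
        lat[, t] <- x
        cnt[, t] <- if (config$observation_model == "multinomial") {
          stats::rmultinom(1, size = config$sequencing_depth, prob = x)[, 1L]
        } else {
          stats::rpois(n, lambda = config$sequencing_depth * x)
        }
        # a sample must carry at least one read to be a sample at all
        if (sum(cnt[, t]) == 0) cnt[which.max(x), t] <- 1
      }
      list(lat = lat, cnt = cnt)
    })
    idx <- col + seq_len(config$n_steps)
    counts[, idx] <- block$cnt
    latent[, idx] <- block$lat
    replicates[idx] <- r
    time_steps[idx] <- seq_len(config$n_steps)
    col <- col + config$n_steps
  }

  if (any(rowSums(counts) == 0))
    warning("OTU(s) extinct in every sample (retained as zeros): ",
            paste(otu_ids[rowSums(counts) == 0], collapse = ", "))

  table <- experiment_table(counts, otu_ids = otu_ids, replicates = replicates,
                            time_steps = time_steps,
                            step_intervals_days = config$step_intervals_days)
  dimnames(latent) <- dimnames(table$counts)
  truth <- structure(list(config = config, latent_series = latent),
                     class = "ground_truth")
  list(table = table, truth = truth)
}

#' Simulation config with planted consortia
#'
#' Builds ground truth for recovery tests: OTUs inside each group interact
#' positively (coefficient `within_strength` for every ordered within-group
#' pair), every diagonal entry is -1 (self-limitation), and all other
#' entries are 0. Equilibrium abundances are log-spaced over one decade.
#'
#' @param n_otus total number of taxa.
#' @param groups list of integer vectors (1-based OTU indices); must be
#'   disjoint. OTUs in no group are independent background taxa.
#' @param within_strength positive within-group interaction rate (default 1).
#' @param equilibrium_abundances optional simplex vector overriding the
#'   default log-spaced (one decade) equilibria. A group holding a dominant
#'   share of the community becomes internally zero-sum under compositional
#'   closure, so recovery scenarios should keep every group a minority.
#' @param seed integer seed stored in the config.
#' @param ... further arguments passed to [simulation_config()]
#'   (e.g. `noise_sigma`, `sequencing_depth`).
#' @return a [simulation_config()].
#' @export
planted_consortia_config <- function(n_otus, groups, within_strength = 1,
                                     equilibrium_abundances = NULL,
                                     seed = 1L, ...) {
  members <- unlist(groups)
  if (anyDuplicated(members)) stop("groups must be disjoint")
  if (length(members) && (min(members) < 1 || max(members) > n_otus))
    stop("group members must be OTU indices in 1..n_otus")
  cmat <- -diag(n_otus)
  for (g in groups) {
    for (i in g) for (j in g) if (i != j) cmat[i, j] <- within_strength
  }
  if (is.null(equilibrium_abundances))
    equilibrium_abundances <- log_spaced_equilibrium(n_otus)
  simulation_config(n_otus, interaction_matrix = cmat,
                    equilibrium_abundances = equilibrium_abundances,
                    seed = seed, ...)
}
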