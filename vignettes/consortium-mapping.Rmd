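---
title: "Mapping bacterial consortia from replicated culture time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping bacterial consortia from replicated culture time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consortmap)
```

## The problem

When an environmental inoculum is sub-cultured many times in parallel on a
selective medium, the taxa that persist are not a random draw: functionally
associated taxa — consortia — rise and fall together across transfers.
`consortmap` identifies such consortia from an OTU count table indexed by
replicate and sub-culturing step. The reference design it emulates is ten
replicate cultures sampled at nine transfer steps (90 samples) with uneven
intervals of 4, 4, 3, 2, 2, 2, 3 and 2 days, sequenced to a fixed depth, with
the analysis restricted to the ~26 most abundant OTUs.

The workflow has four stages:

1. **Replicate QC.** Fluctuation scaling across replicates at a chosen step:
   for each OTU, log10 standard deviation is regressed on log10 mean
   (Taylor's law). Independent Poisson sampling gives slope 1/2; a slope far
   above ~0.6 indicates structured, non-random replicates. Shannon/Simpson
   diversity, richness, Bray-Curtis dissimilarities and ANOSIM round out the
   monitoring statistics.
2. **Correlation.** Within each replicate, each OTU's relative-abundance
   series is demeaned; Pearson correlations of these fluctuations (pooled
   over replicates by default) estimate co-variation. Significance comes
   from two independent nulls — within-replicate time permutation, and
   simulation of independent lognormal count tables — both with the add-one
   convention `p = (1 + hits) / (1 + n)`.
3. **Embedding and consortium detection.** Correlations map linearly to
   distances, `d = 1 - r` (so r = +1 gives d = 0 and r = -1 gives d = 2),
   and OTUs are embedded in 3D by non-metric MDS minimising Kruskal
   stress-1. Consortia are the connected components (two or more members) of
   the graph whose edges are significant positive correlations.
4. **Interaction inference (LIMITS).** Directed interactions are estimated
   under the stochastic discrete Lotka-Volterra model and reported when
   selected in at least half of the bootstrap bags.

## The dLV model and its estimator

The community model for relative abundances $x_i$ over a transfer interval
$\delta t$ (days) is

$$x_i(t + \delta t) \;\propto\; \eta_i(t)\, x_i(t)\,
\exp\!\Big(\delta t \sum_j c_{ij}\,\big(x_j(t) - \langle x_j\rangle\big)\Big),$$

with $\ln \eta_i \sim \mathcal N(0, \sigma^2)$ multiplicative environmental
noise and $\langle x_j \rangle$ the equilibrium abundance set by the carrying
capacity of the environment. After every step the state is renormalised to
the simplex, since only relative abundances are observed.

Taking logs gives a linear regression per taxon: the response is
$y_i = (\ln x_i(t+\delta t) - \ln x_i(t)) / \delta t$ (per-day rates, so the
uneven 4/3/2-day intervals are commensurable) and the predictors are
$x_j(t) - \langle x_j \rangle$, with $\langle x_j \rangle$ estimated by the
per-OTU median (robust to the transient early steps; the mean is available).
Zeros are replaced by half the smallest nonzero relative abundance before
logging. Transitions never span replicate boundaries.

LIMITS fits this regression sparsely: for each target taxon and each of
`n_bags` random half-splits of the transitions, forward stepwise selection
starts from the self-interaction and adds the predictor that most reduces
the *test-half* mean squared error, stopping when the best relative
improvement falls below `improvement_threshold` (default 0.01). Entries are
aggregated by the median across bags; an entry is *significant* when
selected in at least `keep_fraction` (default 0.5) of bags. Because the
coefficients are defined only up to an overall scale, the matrix is reported
with median $|c_{ii}| = 1$.

## Identifiability under compositional closure

Working in relative abundances has hard consequences that any user of the
interaction stage should know; they follow from the closure constraint
$\sum_j x_j = 1$, not from the estimator:

- **Row-shift ambiguity.** The predictor deviations sum to (almost exactly)
  zero, so adding any constant $\lambda_i$ to the whole row $c_{i\cdot}$
  leaves the fit unchanged. A sparse method can therefore recover a row only
  if its true form is the *sparsest representative* of this equivalence
  class. For two taxa the deviations are exactly collinear and the
  off-diagonal coefficient is structurally unidentifiable — the design
  matrix is singular, as the model's own formulation acknowledges.
- **Column shift from renormalisation.** The shared renormalisation term
  contributes, to first order, $-\sum_k e_k c_{kj}$ to every entry of column
  $j$. Planted systems used for recovery testing are therefore chosen
  *column-balanced* ($\sum_k e_k c_{kj} = 0$), e.g. a positive interaction
  cycle with equal equilibria; an unbalanced column's shift is real,
  identifiable signal and any consistent method will report it.
- **Compositional false positives.** Even with no true coupling, closure
  plus noise yields occasional significant entries; with the default
  thresholds the per-entry false-positive rate on such data is calibrated at
  or below roughly 10% (asserted in the test suite). Bag support close to
  the 0.5 cut-off should be read as weak evidence.

The same closure effects shape the correlation stage: a group of taxa
holding a dominant share of the community is internally zero-sum (its
members' relative abundances must compete), and taxa outside strongly
fluctuating groups co-vary as "everyone else". The test suite's planted
consortia are therefore interleaved across the abundance ladder with every
group a minority share, mirroring the empirical observation that dominant
taxa are typically not consortium members. The permutation null is
calibrated against genuinely independent series; data passed through
closure are *not* null for it, because closure induces real negative
co-variation which the test correctly detects.

## The synthetic-data generator

`simulate_experiment()` reproduces the study design: per replicate, an
initial composition drawn from Dirichlet(50 · equilibrium) — a moderate
replicate-to-replicate spread — propagated through the dLV map with the
4,4,3,2,2,2,3,2-day intervals, then observed as counts. Defaults: 10
replicates, 9 steps, `noise_sigma = 0.2` (typical step-to-step lognormal
spread for culture transfers), sequencing depth $10^5$, multinomial
count sampling. A Poisson observation mode (independent per-OTU counts at
rate depth·$x_i$) exists because it is the regime in which replicate
fluctuation scaling has Taylor slope exactly 1/2. One root seed drives
deterministic per-replicate sub-streams, so results cannot depend on
evaluation order.

What the generator does *not* emulate: PCR/primer bias, chimeras and
taxonomic misassignment, overdispersion beyond multinomial sampling,
day-to-day environmental drift shared across replicates, and immigration.
Passing recovery tests on this generator therefore demonstrates correctness
of the inference chain under the model's own assumptions, not robustness to
every artefact of real amplicon data.

## Numerical and design choices

- **Taylor fit**: ordinary least squares of log10 sd on log10 mean, the
  convention in the fluctuation-scaling literature; OTUs with zero mean or
  zero variance are excluded rather than pseudocounted. Fitting on counts is
  the default; relative frequencies are available.
- **Diversity**: Shannon in nats (so uniformity gives $H = \ln$ richness);
  Simpson reported as Gini-Simpson $1 - \sum p^2$ with dominance and
  inverse forms available.
- **NMDS**: `vegan::monoMDS` (global model, Kruskal stress-1, primary
  approach to ties) restarted from a classical-MDS start plus 19 random
  configurations by default; 500 iterations and tolerance 1e-7 per restart.
  The reported stress is recomputed by the package's own
  pool-adjacent-violators evaluator, which is also what makes
  rotation-invariance checks exact. Coordinates are centered, rotated to
  principal axes, and sign-fixed so runs are comparable despite the rigid
  symmetries of the solution. Stress labels use the 0.2 / 0.1 / 0.05 / 0.025
  benchmarks.
- **Distance map**: the endpoint conditions (d = 0 at r = +1, d = 2 at
  r = -1) force $d = 1 - r$; the alternative informal reading "shift the
  coefficients by two units" is incompatible with those endpoints and was
  not adopted.
- **Consortium rule**: connected components at significance level `alpha`
  (default 0.05, permutation p-values; Benjamini-Hochberg available and
  recommended for large pools), with an optional minimum-correlation edge
  filter. Components, not cliques, so a consortium need not be fully
  mutually significant.
- **SparCC-style estimator**: log-ratio variances with the sparse linear
  basis-variance approximation and iterative exclusion of the strongest
  correlated pairs (threshold 0.1); non-positive basis variances fall back
  to Pearson on log counts with a warning. It is depth-invariant by
  construction and preferable to Pearson when abundant taxa dominate.
- **Lognormal null**: $(\mu, \sigma)$ of $\ln(\text{count}+1)$ per OTU;
  zero-heavy OTUs borrow the global median $\sigma$. 10,000 simulations by
  default.
- **Singular designs** in LIMITS fall back to ridge with
  $\lambda = 10^{-6}\,\mathrm{tr}(X^\top X)$.

## Problem sizes in the test suite

The suite exercises the chain at desk scale, chosen as the smallest sizes at
which each property is statistically meaningful: Taylor calibration with 26
OTUs × 10 replicates over 100 seeds; null calibration with 500 simulations
of 199 permutations each; consortium recovery on 12 OTUs (three planted
groups of four, within-group rate 1.5 per day) over 50 seeds; interaction
recovery on 5-OTU column-balanced cycles over 50 seeds with the default 100
bags. The pipeline example runs a 12-OTU community end to end.

## Known limitations

- Interaction coefficients are identified only up to scale and the
  closure ambiguities above; interpret signs and support, not magnitudes.
- Correlation is not interaction: the pipeline reports both precisely so
  that the sparse dLV stage can prune correlation-only associations.
- The LIMITS stage assumes the community is near its equilibria; long
  transients or regime shifts violate the linearisation implicit in using a
  fixed $\langle x_j \rangle$.
- With nine time points per replicate, per-replicate correlation estimates
  are noisy; pooling replicates (the default) assumes replicates share one
  interaction structure.
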