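Package: consortmap
Title: Identification of Bacterial Consortia from Replicated Culture Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and visualizing putative bacterial consortia
    from OTU count tables obtained by replicated sub-culturing of environmental
    communities. Provides replicate-randomness validation by Taylor-law
    fluctuation scaling, OTU-OTU correlation estimation (Pearson on demeaned
    fluctuations or a basic SparCC-style compositional estimator) with
    permutation and lognormal-simulation null models, non-metric
    multidimensional scaling of correlation-derived distances with Kruskal
    stress diagnostics, directed interaction inference under a stochastic
    discrete Lotka-Volterra model via forward stepwise regression with
    bootstrap aggregation (LIMITS), and a stochastic discrete Lotka-Volterra
    simulator with sequencing noise for generating ground-truth test
    communities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    vegan,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
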