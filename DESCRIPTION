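Package: ncdyn
Title: Nanocluster Co-Clustering Dynamics from Single-Molecule
    Localization Microscopy Point Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Spatial statistics for two-color single-molecule localization
    microscopy (SMLM/PALM) localization tables: photoblinking correction by
    spatiotemporal grouping, univariate and bivariate pair-correlation
    functions with Monte Carlo random-labeling envelopes and the
    extent-of-mixing (EOM) statistic, coordinate-based colocalization (CBC)
    with randomization nulls and kurtosis summaries, fixed-radius nanodomain
    detection with inside/outside density enrichment, and time-resolved
    cluster-state analysis (density versus short-range clustering maps, a
    3-state Gaussian mixture classification and Markov transition
    probabilities). Includes seed-reproducible synthetic-data generators
    (Poisson, Thomas, random-labeling mixtures, peripheral and
    domain-enriched two-species patterns, blinking movies, dynamic cluster
    assembly) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    mclust,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
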