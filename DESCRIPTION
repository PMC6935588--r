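Package: hzmove
Title: Detecting and Explaining Hybrid-Zone Movement from Clines,
    Linkage Disequilibrium and Individual-Based Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring spatio-temporal movement of hybrid zones
    along one-dimensional transects. Provides geographic cline fitting
    (tanh sigmoid with exponential tails, Metropolis-Hastings sampling,
    AICc model selection and 2 log-likelihood-unit intervals), a supervised
    maximum-likelihood hybrid index and Bayesian genomic clines for
    per-locus introgression outliers, Ohta's D-statistics variance
    partitioning of two-locus disequilibrium into within- and
    among-population components along a transect, a spatially explicit
    individual-based meta-population simulator with hierarchical
    F-statistics, a contingency analysis tying geographic and genomic
    cline classifications together, and a fully synthetic data generator
    emulating a two-species conifer hybrid zone so the entire pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
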