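Package: omicsclust
Title: Condition Clustering and Significance Testing for Multi-Omics Count Data
Version: 0.1.0
Authors@R:
    person("omicsclust", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify whether samples in gene-by-sample count
    matrices (bulk RNA-seq read counts, proteomics spectral counts) cluster
    by experimental condition. Implements median-of-ratios size-factor
    normalization with a pseudocount rule suited to sparse counts,
    replicate-consistency quality control, complete-linkage hierarchical
    clustering on Euclidean sample distances, and a permutation z-score
    test on mean cophenetic distances that measures clustering by any
    categorical design variable (growth phase, carbon source, ion levels,
    batch). Also provides a doubling-time estimator for OD600 bacterial
    growth curves, linear trend tests for metabolic flux ratios with
    Benjamini-Hochberg FDR correction, and seeded negative-binomial
    simulators with planted condition and batch effects so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
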