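Package: rsfcnet
Title: Graph-Theoretical Analysis of Resting-State Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of resting-state functional MRI (rsfMRI)
    brain networks in small rodent cohorts: nuisance regression, band-pass
    filtering and temporal masking of ROI (region of interest) BOLD time
    series; Pearson connectivity matrices and sparsity-thresholded binary
    graphs; global and nodal topology metrics (degree, clustering,
    efficiency, characteristic path length, greedy modularity) with
    degree-preserving random-network normalization, small-world index, and
    area-under-curve integration over a sparsity grid; group inference by
    mixed ANOVA, FDR-corrected nodal tests, and the permutation-based
    network-based statistic (NBS) with family-wise error control. Includes a
    synthetic-cohort generator with modular small-world covariance and
    planted group effects so the full pipeline is testable without scanner
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    signal,
    pracma,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
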