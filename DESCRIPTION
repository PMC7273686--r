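Package: coocnet
Title: Microbial Co-Occurrence Network Inference Across Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers per-environment microbial co-occurrence networks from
    ESV-by-sample count tables using a permutation/bootstrap (ReBoot)
    significance scheme over Spearman and Bray-Curtis association measures,
    merges measure-specific p-values with Brown's method, thresholds scores
    with a random-matrix-theory spectral criterion, and removes indirect
    associations by network deconvolution. Environment subnetworks are merged
    into a global network and analysed with a downstream ecology layer:
    topology metrics and greedy modularity, generalist/specialist edge
    classification, omission-score localization, taxon-pair
    overrepresentation, hub detection, and negative-edge profiling. A
    synthetic-data module generates multi-environment compositional count
    tables with planted association structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    biomformat,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
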