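Package: coexdiff
Title: Weighted Co-Expression Networks with Differential Betweenness Centrality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end weighted gene co-expression network analysis for
    case-control transcriptomic cohorts: optimal propensity-score cohort
    matching, expression filtering and surrogate-variable adjustment,
    sample-network outlier detection, soft-threshold selection by scale-free
    model fit, topological overlap matrices, hierarchical module detection
    with eigengene-trait statistics, condition-specific networks with
    differential betweenness centrality for coordinator-gene discovery, and
    hypergeometric over-representation plus regulatory-network assembly.
    Includes a synthetic-data generator that plants co-expression modules,
    trait-coupled eigengenes, hidden noise components and outlier samples so
    every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    dplyr,
    fgsea,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
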