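Package: netpharm
Title: Network Pharmacology Screening and Hub-Target Inference for
    Multi-Herb Formulas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a network-pharmacology inference workflow for
    multi-herb traditional-medicine formulas: ADME screening of herb
    ingredients by oral-bioavailability and drug-likeness cutoffs with a
    literature whitelist, construction of the compound-target bipartite
    network and its overlap with disease-associated targets, seed-based
    protein-protein interaction (PPI) networks merged into a core PPI
    network, hub-target selection by six node centralities (degree,
    betweenness, closeness, eigenvector, network centrality and local
    average connectivity) under a strict all-medians rule, and
    hypergeometric over-representation analysis with kappa-statistic
    grouping of enriched terms. Ships a fully parameterised synthetic-data
    generator with planted ground truth (dense PPI module, enriched term,
    disease overlap) so the whole pipeline runs and is benchmarked without
    any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    e1071,
    fgsea,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
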