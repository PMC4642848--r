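Package: netmotif
Title: Subgraph Querying and Motif Significance for Labeled Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact and approximate (wildcard and path-constrained) subgraph
    querying of labeled directed or undirected networks, and statistical
    significance testing of query graphs as network motifs against seven
    random-graph null models (degree-preserving shuffling, Erdos-Renyi,
    Watts-Strogatz, Barabasi-Albert, geometric, forest fire and duplication).
    Reads and writes Cytoscape SIF files with node (.NA) and edge (.EA)
    attribute sidecars, ships a library of canonical regulatory motifs
    (feed-forward loop, bifan, single-input module, dense overlapping
    regulon), and reports network summary metrics (average degree, average
    clustering coefficient, degree assortativity) to guide null-model choice.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
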