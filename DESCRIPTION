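Package: collnet
Title: Species-Collector and Collector Coworking Networks from
    Biological Collection Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses two network models of biological
    collection datasets: the bipartite species-collector network (SCN),
    linking collectors to the taxa they recorded with edge weights equal
    to record co-occurrence counts, and the unipartite collector
    coworking network (CWN), linking collectors who co-authored specimen
    records, with full-count or hyperbolic (1/(n-1)) fractional edge
    weighting.  Includes readers for Darwin Core style occurrence tables,
    collector-name atomization and normalization, taxonomic aggregation
    of species nodes, the case-study analytics (connected components,
    density, betweenness centrality, Louvain communities, team-size
    statistics, island filtering), a synthetic occurrence-data generator
    with planted ground truth, and GraphML/edge-list exporters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    Matrix,
    methods,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
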