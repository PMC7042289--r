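# collnet

Network models of biological collections: who collects what, and who
collects with whom.

A herbarium (or any natural-history collection) is documented by species
occurrence records, each naming the collectors who authored it
(`recordedBy`) and the taxon recorded (`scientificName`). `collnet` turns
a table of such records into two complementary graphs and runs the
social-network analytics that reveal the collection's structure:

* **Species-collector network (SCN)** — a bipartite graph with collector
  nodes u₁…uₙ and taxon nodes v₁…vₘ. Each record with n collectors
  creates (or strengthens) n links, so the biadjacency matrix A holds
  a_ij = the number of records on which collector u_i and taxon v_j
  co-occur. Row i is collector u_i's *species bag*
  σ_ui = [a_i1, …, a_im]; column j is taxon v_j's *quorum*
  ι_vj = [a_1j, …, a_nj]. Species nodes can be aggregated to a higher
  rank (genus, family) by summing quorum vectors within each group.

* **Collector coworking network (CWN)** — a unipartite weighted graph on
  the collectors. Every record whose team has n ≥ 2 members is a distinct
  collaboration act; under hyperbolic weighting it adds
  1/(n − 1) to each of its n(n − 1)/2 pairs,

      w_(i,j) = Σ_k δ_i^(k) δ_j^(k) / (n^(k) − 1),

  so a two-person record contributes the maximum weight 1 and large teams
  dilute individual ties. A full-count scheme (1 per co-appearance) is
  also available. The adjacency matrix is symmetric with zero diagonal;
  single-collector records create nodes but no edges, and degree-zero
  nodes are the *individualist* collectors.

Around the models: Darwin Core style table reading, collector-name
atomization/normalization/disambiguation (`"Proença, C.E.B."` →
`proenca,ceb`), record filtering, connected components, whole-graph and
giant-component density, average degree, betweenness centrality, Louvain
community detection, team-size statistics, island filtering for display,
GraphML/edge-list export, a YAML-driven command-line pipeline
(`inst/cli/collnet.R`), and a synthetic occurrence-data generator with
planted ground truth (interest communities, coworking groups,
individualists, name-variant noise) for testing every step without any
download.

## Worked example

```r
library(collnet)

# a 2,000-record synthetic herbarium table with known ground truth
d <- generate_occurrences(generator_config(n_records = 2000, seed = 1))
paths <- write_synthetic_dataset(d, "demo")

records <- resolve_collectors(read_occurrences(paths[["occurrences"]]),
                              name_map = read_name_map(paths[["name_map"]]))

kept <- filter_records(records, record_filter_config(allowed_ranks = "species"))$kept
scn <- build_scn(kept)
scn
#> Species-collector network (bipartite)
#>   collectors: 189  taxa: 391  edges: 2699
#>   taxonomic resolution: species

aggregate_scn(scn, taxonomy_from_records(kept), "family")
#> Species-collector network (bipartite)
#>   collectors: 189  taxa: 20  edges: 924
#>   taxonomic resolution: family

teams <- extract_teams(records)
cwn <- build_cwn(teams, "hyperbolic")
cwn
#> Collector coworking network (hyperbolic weighting)
#>   collectors: 189  edges: 1439
#>   individualists: 68

team_size_stats(teams)$mean                   # 1.716
graph_density(cwn)                            # 0.081
graph_density(cwn, "giant_component")         # 0.198
detect_communities(cwn, seed = 1)
#> Community partition: 72 communities, modularity 0.6374 (seed 1)
round(head(sort(betweenness_centrality(cwn), decreasing = TRUE), 4), 3)
#>  lilan,ej rosil,mkp   perei,y   mosil,b
#>     0.019     0.012     0.010     0.010
```

Reading the numbers: the SCN edge count (2,699) is the number of distinct
collector–species associations; a collector's species-bag sum is exactly
their record count. The CWN has 68 individualists (36% of nodes, close to
the generator's planted 39.5% minus collectors who never appear), the mean
team size realises the configured 1.73 law, and density rises from 0.081
to 0.198 when isolated and peripheral components are excluded by scoping
to the giant component. The 72 "communities" include every individualist
as a singleton; the four planted coworking groups dominate the modularity
(0.637). Betweenness (normalized, unweighted shortest paths) ranks the
bridge collectors.

The same pipeline runs from a shell:

```sh
Rscript inst/cli/collnet.R build --config run.yaml
Rscript inst/cli/collnet.R stats --graph collnet-out/cwn.graphml --seed 1
```

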