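test_that("components are found and ordered deterministically", {
  g <- igraph::make_graph(~ A - B, B - C) + igraph::vertices("D")
  comp <- connected_components(g)
  expect_equal(comp$n_components, 2)
  expect_equal(comp$components[[1]], c("A", "B", "C"))
  expect_equal(comp$components[[2]], "D")

  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(edgeless)$name <- c("x", "y", "z")
  expect_equal(connected_components(edgeless)$sizes, c(1, 1, 1))

  # equal-sized components break ties on smallest member id
  g2 <- igraph::make_graph(~ b - c, a - d)
  expect_equal(connected_components(g2)$components,
               list(c("a", "d"), c("b", "c")))
})

test_that("components match a union-find oracle on random graphs", {
  set.seed(81)
  for (i in 1:15) {
    g <- random_named_graph(30, runif(1, 0.02, 0.15))
    ends <- graph_edge_ends(g)
    oracle <- oracle_components(igraph::V(g)$name, ends$from, ends$to)
    got <- connected_components(g)$components
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(oracle, paste, collapse = ","))
  }
})

test_that("density follows the bipartite and unipartite formulas", {
  # complete bipartite 2x3 and a triangle both have density 1
  k23 <- toy_records(as.list(rep(c("a,x", "b,x"), 3)),
                     taxa = rep(c("T a", "T b", "T c"), each = 2))
  expect_equal(graph_density(build_scn(k23)), 1)
  tri <- build_cwn(tibble::tibble(record_id = "r1",
                                  members = list(c("a,x", "b,x", "c,x")),
                                  size = 3L))
  expect_equal(graph_density(tri), 1)

  # hand-computed |E|/(n m): 3 edges over 2x2
  fix <- toy_records(list(c("a,x", "b,x"), "a,x"), taxa = c("T a", "T b"))
  expect_equal(graph_density(build_scn(fix)), 3 / 4)

  single <- build_cwn(tibble::tibble(record_id = "r1",
                                     members = list("a,x"), size = 1L))
  expect_error(graph_density(single), "fewer than 2")
})

test_that("density rises when isolates are excluded via the giant component", {
  recs <- toy_records(list(c("a,x", "b,x"), c("b,x", "c,x"), "d,x", "e,x"))
  cwn <- build_cwn(extract_teams(recs))
  expect_lt(graph_density(cwn, "whole"),
            graph_density(cwn, "giant_component"))
  expect_equal(graph_density(cwn, "giant_component"), 2 / 3)
})

test_that("average degree matches direct degree sums", {
  star <- igraph::make_star(5, "undirected")
  igraph::V(star)$name <- letters[1:5]
  expect_equal(average_degree(star), 1.6)
  edgeless <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(edgeless)$name <- letters[1:4]
  expect_equal(average_degree(edgeless), 0)

  set.seed(91)
  for (i in 1:10) {
    g <- random_named_graph(25, runif(1, 0.05, 0.3))
    expect_equal(average_degree(g), mean(igraph::degree(g)))
  }

  scn <- build_scn(toy_records(list(c("a,x", "b,x"), "a,x"),
                               taxa = c("T a", "T b")))
  deg <- average_degree(scn)
  expect_equal(deg$overall, 2 * 3 / 4)
  expect_equal(deg$collectors, 3 / 2)
})

test_that("betweenness matches the exhaustive shortest-path oracle", {
  # path A-B-C: B intermediates the single pair
  pth <- igraph::make_graph(~ A - B, B - C)
  expect_equal(unname(betweenness_centrality(pth)["B"]), 1)
  expect_equal(unname(betweenness_centrality(pth)[c("A", "C")]), c(0, 0))

  # every leaf of a star scores 0
  star <- igraph::make_star(6, "undirected")
  igraph::V(star)$name <- letters[1:6]
  expect_equal(unname(betweenness_centrality(star)[-1]), rep(0, 5))

  set.seed(101)
  for (i in 1:12) {
    g <- random_named_graph(12, runif(1, 0.15, 0.4))
    ends <- graph_edge_ends(g)
    oracle <- oracle_betweenness(igraph::V(g)$name, ends$from, ends$to)
    got <- betweenness_centrality(g)
    expect_equal(got[names(oracle)], oracle, tolerance = 1e-10)
    raw <- betweenness_centrality(g, normalized = FALSE)
    expect_equal(raw[names(oracle)], oracle * (12 - 1) * (12 - 2) / 2,
                 tolerance = 1e-10)
  }
})

test_that("Louvain separates disjoint modules and is seed-reproducible", {
  two_tri <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
  part <- detect_communities(two_tri, seed = 4)
  expect_equal(part$n_communities, 2)
  expect_equal(length(unique(part$assignment[c("a", "b", "c")])), 1)
  expect_equal(length(unique(part$assignment[c("d", "e", "f")])), 1)
  expect_gte(part$modularity, 0)

  set.seed(1)  # outer RNG state must not matter
  p1 <- detect_communities(two_tri, seed = 9)
  set.seed(2)
  p2 <- detect_communities(two_tri, seed = 9)
  expect_identical(p1$assignment, p2$assignment)
})

test_that("Louvain recovers a planted two-block partition", {
  set.seed(111)
  g <- igraph::sample_sbm(40, matrix(c(0.9, 0.02, 0.02, 0.9), 2),
                          c(20, 20))
  igraph::V(g)$name <- sprintf("n%02d", 1:40)
  truth <- setNames(rep(1:2, each = 20), igraph::V(g)$name)
  part <- detect_communities(g, seed = 5)
  expect_equal(ground_truth_eval(part, truth), 1)
})

test_that("team size statistics are exact", {
  teams <- tibble::tibble(record_id = c("r1", "r2", "r3"),
                          members = list("a,x", "b,x", c("a,x", "b,x")),
                          size = c(1L, 1L, 2L))
  stats <- team_size_stats(teams)
  expect_equal(stats$mean, 4 / 3)
  expect_equal(stats$histogram$n, c(2L, 1L))
  expect_error(team_size_stats(teams[0, ]), "nonempty")
})

test_that("island filtering drops weak edges then low-scoring islands", {
  teams <- tibble::tibble(
    record_id = sprintf("r%d", 1:17),
    members = c(rep(list(c("a,x", "b,x")), 12),
                rep(list(c("c,x", "d,x")), 5)),
    size = 2L)
  cwn <- build_cwn(teams)  # w(a,b) = 12, w(c,d) = 5

  ident <- island_filter(cwn, 0, 0)
  expect_equal(as.matrix(ident$graph$adjacency), as.matrix(cwn$adjacency))

  weak <- island_filter(cwn, 10, 0)
  expect_equal(Matrix::nnzero(weak$graph$adjacency) / 2, 1)

  # node weights: records per collector; island {a,b} scores 24, each
  # singleton from the split {c},{d} scores 5
  counts <- collector_record_counts(teams)
  isl <- island_filter(cwn, 10, 600, node_weight = counts)
  expect_equal(nrow(isl$islands), 3)
  expect_equal(sum(isl$islands$kept), 0)
  isl2 <- island_filter(cwn, 10, 20, node_weight = counts)
  expect_setequal(isl2$kept_nodes, c("a,x", "b,x"))
  expect_true(all(isl2$islands$score[isl2$islands$kept] >= 20))

  expect_error(island_filter(cwn, 0, 0, node_weight = c("a,x" = 1)),
               "undefined")
})
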