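test_that("one record with n collectors creates n unit-weight links", {
  recs <- toy_records(list(c("a,b", "b,c")), taxa = "Myrcia tomentosa")
  scn <- build_scn(recs)
  A <- as.matrix(scn$biadjacency)
  expect_equal(dim(A), c(2, 1))
  expect_equal(unname(A[, 1]), c(1, 1))

  # repeated association strengthens the single link
  recs3 <- toy_records(list("a,b", "a,b", "a,b"), taxa = rep("X y", 3))
  expect_equal(as.numeric(build_scn(recs3)$biadjacency["a,b", "X y"]), 3)
})

test_that("empty input and precondition violations are handled", {
  empty <- toy_records(list(), taxa = character(0))
  scn <- build_scn(empty)
  expect_equal(dim(scn$biadjacency), c(0, 0))

  bad <- toy_records(list("a,b", character(0)), taxa = c("X y", "Z w"))
  expect_error(build_scn(bad), "r002")
})

test_that("species bags and quorums are the rows and columns of A", {
  recs <- toy_records(
    list(c("a,x", "b,x"), "a,x", c("b,x", "c,x"), "a,x", "c,x"),
    taxa = c("T one", "T two", "T one", "T one", "T three"))
  scn <- build_scn(recs)

  bag <- species_bag(scn, "a,x")
  expect_equal(length(bag), ncol(scn$biadjacency))
  expect_equal(unname(bag[c("T one", "T two", "T three")]), c(2, 1, 0))
  # bag sum == the collector's record count
  expect_equal(sum(bag), 3)

  q <- quorum(scn, "T one")
  expect_equal(length(q), nrow(scn$biadjacency))
  expect_equal(unname(q[c("a,x", "b,x", "c,x")]), c(2, 2, 1))

  # transpose identity
  for (tx in colnames(scn$biadjacency)) {
    for (cl in rownames(scn$biadjacency)) {
      expect_equal(quorum(scn, tx)[[cl]], species_bag(scn, cl)[[tx]])
    }
  }

  expect_error(species_bag(scn, "nobody,x"), "Unknown collector")
  expect_error(quorum(scn, "Nothing at all"), "Unknown taxon")
})

test_that("biadjacency matches the brute-force tally on random fixtures", {
  set.seed(21)
  for (i in 1:25) {
    recs <- random_records(sample(50, 1))
    scn <- build_scn(recs)
    M <- oracle_scn_tally(recs$collector_ids, recs$taxon_name)
    A <- as.matrix(scn$biadjacency)[rownames(M), colnames(M), drop = FALSE]
    expect_equal(unname(A), unname(M))
  }
})

test_that("aggregation sums quorum vectors and conserves weight", {
  recs <- toy_records(
    list("a,x", "a,x", "a,x", "a,x", "a,x", "b,x"),
    taxa = c("M alba", "M alba", "M rubra", "M rubra", "M rubra", "Q major"))
  scn <- build_scn(recs)
  tax <- c("M alba" = "Myrtaceae", "M rubra" = "Myrtaceae",
           "Q major" = "Vochysiaceae")
  agg <- aggregate_scn(scn, tax, "family")
  expect_equal(agg$resolution, "family")
  expect_equal(as.numeric(agg$biadjacency["a,x", "Myrtaceae"]), 5)
  expect_equal(sum(agg$biadjacency), sum(scn$biadjacency))
  expect_equal(rownames(agg$biadjacency), rownames(scn$biadjacency))

  # identity grouping is isomorphic to the input
  ident <- setNames(colnames(scn$biadjacency), colnames(scn$biadjacency))
  same <- aggregate_scn(scn, ident, scn$resolution)
  expect_equal(as.matrix(same$biadjacency), as.matrix(scn$biadjacency))

  expect_error(aggregate_scn(scn, tax[-1], "family"), "M alba")
})

test_that("aggregation conserves totals and row sums on random fixtures", {
  set.seed(31)
  for (i in 1:10) {
    recs <- random_records(40, n_taxa = 10)
    scn <- build_scn(recs)
    taxa <- colnames(scn$biadjacency)
    tax <- setNames(sample(paste0("G", 1:3), length(taxa), replace = TRUE),
                    taxa)
    agg <- aggregate_scn(scn, tax, "group")
    expect_equal(sum(agg$biadjacency), sum(scn$biadjacency))
    expect_equal(rowSums(as.matrix(agg$biadjacency)),
                 rowSums(as.matrix(scn$biadjacency)))
  }
})

test_that("edge filtering drops weak ties and optionally isolates", {
  recs <- toy_records(
    c(rep(list("a,x"), 19), rep(list("b,x"), 20), rep(list("c,x"), 25),
      list("d,x")),
    taxa = c(rep("T a", 19), rep("T b", 20), rep("T c", 25), "T d"))
  scn <- build_scn(recs)
  expect_equal(Matrix::nnzero(filter_scn_edges(scn, 1)$biadjacency), 4)
  f20 <- filter_scn_edges(scn, 20)
  expect_equal(Matrix::nnzero(f20$biadjacency), 2)
  # isolates persist unless dropped
  expect_equal(nrow(f20$biadjacency), 4)
  f20d <- filter_scn_edges(scn, 20, drop_isolates = TRUE)
  expect_equal(sort(rownames(f20d$biadjacency)), c("b,x", "c,x"))
  g <- as.igraph(f20d)
  expect_true(all(igraph::degree(g) > 0))
})

test_that("bipartiteness holds after build, aggregation, and filtering", {
  set.seed(41)
  recs <- random_records(40, n_taxa = 8)
  scn <- build_scn(recs)
  taxa <- colnames(scn$biadjacency)
  agg <- aggregate_scn(scn, setNames(sample(paste0("G", 1:3), length(taxa),
                                            replace = TRUE), taxa), "group")
  for (m in list(scn, agg, filter_scn_edges(scn, 2))) {
    g <- as.igraph(m)
    expect_true(igraph::is_bipartite(g))
    ends <- igraph::ends(g, igraph::E(g))
    types <- setNames(igraph::V(g)$type, igraph::V(g)$name)
    expect_true(all(types[ends[, 1]] != types[ends[, 2]]))
    expect_true(all(m$biadjacency@x > 0))
  }
})
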