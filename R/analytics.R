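#' Convert collnet models to igraph graphs
#'
#' `scn` objects become bipartite graphs (logical `type` vertex attribute,
#' `FALSE` for collectors, `TRUE` for taxa, plus a `part` label attribute);
#' `cwn` objects become undirected weighted graphs including isolated
#' nodes.  All analytics below accept either the model object or the
#' igraph graph.
#'
#' @param x An `scn` or `cwn` object.
#' @param ... Unused.
#' @return An igraph graph.
#' @name as.igraph.collnet
NULL

#' @rdname as.igraph.collnet
#' @export
as.igraph.scn <- function(x, ...) {
  g <- igraph::graph_from_biadjacency_matrix(x$biadjacency, weighted = TRUE)
  igraph::V(g)$part <- ifelse(igraph::V(g)$type, "taxon", "collector")
  g
}

#' @rdname as.igraph.collnet
#' @export
as.igraph.cwn <- function(x, ...) {
  igraph::graph_from_adjacency_matrix(x$adjacency, mode = "undirected",
                                      weighted = TRUE)
}

as_collnet_igraph <- function(x) {
  if (igraph::is_igraph(x)) x else igraph::as.igraph(x)
}

#' Connected components with deterministic ordering
#'
#' Components are ordered by decreasing size, ties broken by the
#' lexicographically smallest member id, so that labels c_1, c_2, ... are
#' stable across runs.  For bipartite graphs the per-component node counts
#' by part are summarised alongside.
#'
#' @param x An `scn`, `cwn` or igraph object.
#' @return A list with `components` (list of sorted member-id vectors),
#'   `sizes`, `n_components`, and `summary` (tibble with component index,
#'   size and, for bipartite graphs, collector/taxon counts).
#' @export
connected_components <- function(x) {
  g <- as_collnet_igraph(x)
  comp <- igraph::components(g)
  members <- split(igraph::V(g)$name, comp$membership)
  members <- lapply(members, sort)
  ord <- order(-lengths(members),
               vapply(members, `[`, "", 1))
  members <- unname(members[ord])

  summary <- tibble(component = seq_along(members),
                    size = lengths(members))
  if ("type" %in% igraph::vertex_attr_names(g)) {
    types <- setNames(igraph::V(g)$type, igraph::V(g)$name)
    summary$collectors <- vapply(members, function(m) sum(!types[m]), 0L)
    summary$taxa <- vapply(members, function(m) sum(types[m]), 0L)
  }
  list(components = members, sizes = lengths(members),
       n_components = length(members), summary = summary)
}

#' Network density
#'
#' For a unipartite graph the density is 2|E| / (n (n - 1)); for a
#' bipartite graph it is |E| / (n m) with n collectors and m taxa (the
#' fraction of possible collector-taxon ties realised).  `scope =
#' "giant_component"` computes the same quantity on the subgraph induced
#' by the largest component, which is larger whenever isolated nodes or
#' small components exist.
#'
#' @param x An `scn`, `cwn` or igraph object.
#' @param scope `"whole"` or `"giant_component"`.
#' @return A single number.
#' @export
graph_density <- function(x, scope = c("whole", "giant_component")) {
  scope <- match.arg(scope)
  g <- as_collnet_igraph(x)
  if (igraph::vcount(g) == 0) abort("Density is undefined for an empty graph.")
  if (scope == "giant_component") {
    comp <- connected_components(g)
    g <- igraph::induced_subgraph(g, comp$components[[1]])
  }
  if ("type" %in% igraph::vertex_attr_names(g)) {
    n <- sum(!igraph::V(g)$type); m <- sum(igraph::V(g)$type)
    if (n == 0 || m == 0) abort("Bipartite density needs both parts nonempty.")
    igraph::ecount(g) / (n * m)
  } else {
    n <- igraph::vcount(g)
    if (n < 2) abort("Unipartite density is undefined for fewer than 2 nodes.")
    2 * igraph::ecount(g) / (n * (n - 1))
  }
}

#' Average degree
#'
#' Overall average degree 2|E| / |V|; for bipartite graphs the per-part
#' averages (|E| / n collectors, |E| / m taxa) are reported as well.
#'
#' @param x An `scn`, `cwn` or igraph object.
#' @return For unipartite input, a number.  For bipartite input, a list
#'   with `overall`, `collectors`, `taxa`.
#' @export
average_degree <- function(x) {
  g <- as_collnet_igraph(x)
  if (igraph::vcount(g) == 0) abort("Average degree needs a nonempty graph.")
  overall <- 2 * igraph::ecount(g) / igraph::vcount(g)
  if ("type" %in% igraph::vertex_attr_names(g)) {
    list(overall = overall,
         collectors = igraph::ecount(g) / sum(!igraph::V(g)$type),
         taxa = igraph::ecount(g) / sum(igraph::V(g)$type))
  } else {
    overall
  }
}

#' Betweenness centrality
#'
#' Freeman betweenness c_B(v) = sum over node pairs (s, t) of the fraction
#' of shortest s-t paths passing through v, endpoints excluded, pairs in
#' different components contributing zero.  Paths are unweighted (edge
#' weights play no role in path length), matching how bridge collectors
#' are ranked in collection coworking networks.  Normalized scores divide
#' by (n - 1)(n - 2) / 2, putting them in [0, 1].
#'
#' @param x An `scn`, `cwn` or igraph object.
#' @param normalized Divide by the number of possible pairs (default TRUE).
#' @return Named numeric vector of per-node scores.
#' @export
betweenness_centrality <- function(x, normalized = TRUE) {
  g <- as_collnet_igraph(x)
  igraph::betweenness(g, directed = FALSE, weights = NA,
                      normalized = normalized)
}

#' Louvain community detection
#'
#' Runs the Louvain heuristic for Newman modularity maximization on the
#' (weighted) graph, with edge weights used as tie strengths.  The run is
#' reproducible: the given seed is applied immediately before the
#' heuristic, so a fixed seed always returns the same partition.
#'
#' @param x An `scn`, `cwn` or igraph object (undirected).
#' @param seed Integer seed for the heuristic's randomized node order.
#' @param resolution Resolution parameter of the modularity objective
#'   (1 = classic Newman modularity).
#' @return A list of class `community_partition` with `assignment` (named
#'   integer vector, node -> community id), `modularity`, `n_communities`,
#'   `seed` and `resolution`.
#' @export
detect_communities <- function(x, seed = 1L, resolution = 1) {
  g <- as_collnet_igraph(x)
  w <- if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight else NULL
  cl <- withr::with_seed(seed,
    igraph::cluster_louvain(g, weights = w, resolution = resolution))
  assignment <- setNames(as.integer(igraph::membership(cl)),
                         igraph::V(g)$name)
  structure(list(assignment = assignment,
                 modularity = max(cl$modularity),
                 n_communities = length(unique(assignment)),
                 seed = seed, resolution = resolution),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Community partition:", x$n_communities, "communities, modularity",
      round(x$modularity, 4), "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Team size statistics
#'
#' Exact per-size record counts and the mean team size.  In herbarium
#' datasets the count of records decays roughly log-linearly with team
#' size and the mean sits well below 2, because most records are
#' non-collaborative.
#'
#' @param teams Team tibble from [extract_teams()].
#' @return A list with `histogram` (tibble: size, n) and `mean`.
#' @export
team_size_stats <- function(teams) {
  if (nrow(teams) == 0) abort("team_size_stats needs a nonempty team set.")
  tab <- table(teams$size)
  list(histogram = tibble(size = as.integer(names(tab)),
                          n = as.integer(tab)),
       mean = mean(teams$size))
}

#' Total record count per collector
#'
#' The number of records each collector appears on — the default node
#' weight for [island_filter()] (node importance proportional to how often
#' a collector appears on records).
#'
#' @param teams Team tibble from [extract_teams()].
#' @return Named numeric vector, collector id -> record count.
#' @export
collector_record_counts <- function(teams) {
  members <- unlist(teams$members, use.names = FALSE)
  tab <- table(members)
  setNames(as.numeric(tab), names(tab))
}

#' Island filtering of a coworking network
#'
#' The display-filtering routine for large CWNs: drop edges below a weight
#' threshold, recompute connected components (the "islands" this creates),
#' score every island by summing a node weight over its members, and keep
#' only islands at or above a score threshold.  With both thresholds at
#' zero this is the identity.
#'
#' @param cwn A `cwn` object.
#' @param min_edge_weight Edges with weight strictly below this are dropped.
#' @param min_island_score Islands with total node weight strictly below
#'   this are dropped.
#' @param node_weight Named numeric vector over all CWN nodes; defaults to
#'   1 per node if `NULL`.  Use [collector_record_counts()] for the
#'   record-count weighting.
#' @return A list with `graph` (the filtered `cwn`, restricted to nodes of
#'   surviving islands), `islands` (tibble: island index, size, score,
#'   kept) and `kept_nodes`.
#' @export
island_filter <- function(cwn, min_edge_weight = 0, min_island_score = 0,
                          node_weight = NULL) {
  stopifnot(inherits(cwn, "cwn"))
  nodes <- rownames(cwn$adjacency)
  if (is.null(node_weight)) node_weight <- setNames(rep(1, length(nodes)), nodes)
  missing <- setdiff(nodes, names(node_weight))
  if (length(missing) > 0) {
    abort(paste0("node_weight undefined for ", length(missing), " node(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }

  A <- cwn$adjacency
  A@x[A@x < min_edge_weight] <- 0
  A <- Matrix::drop0(A)
  filtered <- structure(list(adjacency = A, weighting = cwn$weighting),
                        class = "cwn")

  comp <- connected_components(filtered)
  scores <- vapply(comp$components, function(m) sum(node_weight[m]), 0)
  kept <- scores >= min_island_score
  kept_nodes <- unlist(comp$components[kept], use.names = FALSE)
  if (is.null(kept_nodes)) kept_nodes <- character(0)

  A_kept <- A[kept_nodes, kept_nodes, drop = FALSE]
  list(
    graph = structure(list(adjacency = A_kept, weighting = cwn$weighting),
                      class = "cwn"),
    islands = tibble(island = seq_along(comp$components),
                     size = comp$sizes, score = scores, kept = kept),
    kept_nodes = kept_nodes
  )
}
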