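# Brute-force oracles, deliberately independent of the package internals:
# plain loops and base R only.

# Dense (collector x taxon) co-occurrence tally, one increment per
# (record, collector) incidence.
oracle_scn_tally <- function(collector_lists, taxa) {
  collectors <- sort(unique(unlist(collector_lists)))
  taxa_set <- sort(unique(taxa))
  M <- matrix(0, length(collectors), length(taxa_set),
              dimnames = list(collectors, taxa_set))
  for (k in seq_along(collector_lists)) {
    for (u in collector_lists[[k]]) {
      M[u, taxa[k]] <- M[u, taxa[k]] + 1
    }
  }
  M
}

# Pair co-appearance counts over teams (full-count CWN semantics).
oracle_pair_counts <- function(member_lists) {
  counts <- list()
  for (m in member_lists) {
    m <- unique(m)
    if (length(m) < 2) next
    for (a in seq_len(length(m) - 1)) {
      for (b in seq(a + 1, length(m))) {
        key <- paste(sort(c(m[a], m[b])), collapse = "\r")
        counts[[key]] <- (counts[[key]] %||% 0) + 1
      }
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Union-find connected components from an edge list over a node set.
oracle_components <- function(nodes, edges_from, edges_to) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(edges_from)) {
    ra <- find(edges_from[k]); rb <- find(edges_to[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, "")
  unname(lapply(split(nodes, roots), sort))
}

# Exhaustive betweenness: enumerate every shortest path between every
# pair with BFS distances + recursive backtracking.
oracle_betweenness <- function(nodes, edges_from, edges_to, normalized = TRUE) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_along(edges_from)) {
    adj[[edges_from[k]]] <- c(adj[[edges_from[k]]], edges_to[k])
    adj[[edges_to[k]]] <- c(adj[[edges_to[k]]], edges_from[k])
  }
  bfs_dist <- function(s) {
    d <- stats::setNames(rep(Inf, length(nodes)), nodes)
    d[s] <- 0; q <- s
    while (length(q) > 0) {
      cur <- q[1]; q <- q[-1]
      for (nb in adj[[cur]]) {
        if (is.infinite(d[nb])) { d[nb] <- d[cur] + 1; q <- c(q, nb) }
      }
    }
    d
  }
  all_shortest_paths <- function(s, t, d) {
    if (is.infinite(d[t])) return(list())
    extend <- function(path) {
      cur <- path[length(path)]
      if (cur == t) return(list(path))
      out <- list()
      for (nb in adj[[cur]]) {
        if (d[nb] == d[cur] + 1 && d[nb] <= d[t]) {
          out <- c(out, extend(c(path, nb)))
        }
      }
      out
    }
    extend(s)
  }
  score <- stats::setNames(rep(0, length(nodes)), nodes)
  for (a in seq_len(length(nodes) - 1)) {
    for (b in seq(a + 1, length(nodes))) {
      s <- nodes[a]; t <- nodes[b]
      d <- bfs_dist(s)
      paths <- all_shortest_paths(s, t, d)
      if (length(paths) == 0) next
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        score[inner] <- score[inner] + 1 / length(paths)
      }
    }
  }
  n <- length(nodes)
  if (normalized && n > 2) score <- score / ((n - 1) * (n - 2) / 2)
  score
}
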