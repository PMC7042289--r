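xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

#' Extract the weighted edge list of a model
#'
#' @param x An `scn` or `cwn` object.
#' @return For an SCN, a tibble `collector`, `taxon`, `weight`; for a CWN
#'   a tibble `from`, `to`, `weight` with `from < to`.  Rows are sorted by
#'   node ids so exports are stable and diffable.
#' @export
edge_list <- function(x) {
  if (inherits(x, "scn")) {
    A <- methods::as(x$biadjacency, "TsparseMatrix")
    out <- tibble(collector = rownames(A)[A@i + 1L],
                  taxon = colnames(A)[A@j + 1L],
                  weight = A@x)
    out[order(out$collector, out$taxon), ]
  } else if (inherits(x, "cwn")) {
    A <- methods::as(x$adjacency, "TsparseMatrix")
    keep <- A@i < A@j
    from <- rownames(A)[A@i[keep] + 1L]
    to <- colnames(A)[A@j[keep] + 1L]
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
    out <- tibble(from = from, to = to, weight = A@x[keep])
    out[order(out$from, out$to), ]
  } else {
    abort("edge_list expects an scn or cwn object.")
  }
}

#' Write a model's weighted edge list as tab-separated text
#'
#' @param x An `scn` or `cwn` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  readr::write_tsv(edge_list(x), path, progress = FALSE)
  invisible(path)
}

#' Write a model as GraphML
#'
#' Emits standards-conforming GraphML with node attributes (`part` for
#' bipartite SCNs, plus any supplied per-node attributes such as record
#' counts or community ids) and double-typed edge weights serialized at
#' full precision (17 significant digits), so that a write/read round trip
#' reproduces every weight exactly.
#'
#' @param x An `scn` or `cwn` object.
#' @param path Output path.
#' @param node_attrs Optional named list of named vectors: per-node
#'   attributes keyed by node id.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(x, path, node_attrs = NULL) {
  if (inherits(x, "scn")) {
    nodes <- c(rownames(x$biadjacency), colnames(x$biadjacency))
    part <- c(rep("collector", nrow(x$biadjacency)),
              rep("taxon", ncol(x$biadjacency)))
    el <- edge_list(x)
    edges <- cbind(el$collector, el$taxon)
    weights <- el$weight
  } else if (inherits(x, "cwn")) {
    nodes <- rownames(x$adjacency)
    part <- NULL
    el <- edge_list(x)
    edges <- cbind(el$from, el$to)
    weights <- el$weight
  } else {
    abort("write_graphml expects an scn or cwn object.")
  }

  keys <- c('<key id="w" for="edge" attr.name="weight" attr.type="double"/>')
  if (!is.null(part)) {
    keys <- c(keys,
              '<key id="part" for="node" attr.name="part" attr.type="string"/>')
  }
  attr_keys <- character(0)
  if (!is.null(node_attrs)) {
    attr_keys <- sprintf(
      '<key id="na%d" for="node" attr.name="%s" attr.type="%s"/>',
      seq_along(node_attrs), xml_escape(names(node_attrs)),
      vapply(node_attrs, function(v) {
        if (is.numeric(v)) "double" else "string"
      }, ""))
    keys <- c(keys, attr_keys)
  }

  node_lines <- vapply(seq_along(nodes), function(i) {
    data <- character(0)
    if (!is.null(part)) {
      data <- sprintf('<data key="part">%s</data>', part[i])
    }
    if (!is.null(node_attrs)) {
      data <- c(data, vapply(seq_along(node_attrs), function(a) {
        v <- node_attrs[[a]][[nodes[i]]]
        val <- if (is.numeric(v)) sprintf("%.17g", v) else xml_escape(as.character(v))
        sprintf('<data key="na%d">%s</data>', a, val)
      }, ""))
    }
    paste0('    <node id="', xml_escape(nodes[i]), '">',
           paste(data, collapse = ""), "</node>")
  }, "")

  edge_lines <- if (nrow(edges) > 0) {
    sprintf('    <edge source="%s" target="%s"><data key="w">%.17g</data></edge>',
            xml_escape(edges[, 1]), xml_escape(edges[, 2]), weights)
  } else character(0)

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<graphml xmlns="http://graphml.graphdrawing.org/xmlns" ',
           'xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance" ',
           'xsi:schemaLocation="http://graphml.graphdrawing.org/xmlns ',
           'http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd">'),
    paste0("  ", keys),
    '  <graph id="G" edgedefault="undirected">',
    node_lines, edge_lines,
    "  </graph>", "</graphml>"
  ), path, useBytes = TRUE)
  invisible(path)
}

#' Read a GraphML file written by write_graphml()
#'
#' @param path GraphML path.
#' @return An igraph graph (undirected, weighted; bipartite SCN exports
#'   carry `part` and a logical `type` vertex attribute).
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (!"name" %in% igraph::vertex_attr_names(g) &&
      "id" %in% igraph::vertex_attr_names(g)) {
    igraph::V(g)$name <- igraph::V(g)$id
  }
  if ("part" %in% igraph::vertex_attr_names(g)) {
    igraph::V(g)$type <- igraph::V(g)$part == "taxon"
  }
  g
}

#' Write a per-node metrics table
#'
#' @param metrics Named list of named vectors (e.g. degree, betweenness,
#'   community, record count), all keyed by node id.
#' @param path Output path (tab-separated).
#' @return The assembled tibble, invisibly.
#' @export
write_node_table <- function(metrics, path) {
  nodes <- sort(unique(unlist(lapply(metrics, names))))
  out <- tibble(node = nodes)
  for (nm in names(metrics)) {
    out[[nm]] <- unname(metrics[[nm]][nodes])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}
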