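#' Build a species-collector network (SCN)
#'
#' The SCN is a bipartite graph with one node set for collectors and one
#' for taxa.  Every record listing n collectors creates (or strengthens) n
#' links, one from each collector to the recorded taxon, so the weight of
#' edge (u_i, v_j) — element a_ij of the biadjacency matrix A — is the
#' number of records in which collector u_i and taxon v_j co-occur.  All
#' taxon nodes share one taxonomic rank, the network's *resolution*.
#'
#' Records violating the preconditions (no collector ids, blank taxon) make
#' the builder fail with the offending record ids; run [filter_records()]
#' first to drop them deliberately.
#'
#' @param records Resolved occurrence tibble ([resolve_collectors()]); every
#'   row must have at least one collector id and a nonblank taxon name.
#' @param resolution Rank label carried by all taxon nodes
#'   (default `"species"`).
#' @return An object of class `scn`: a list with `biadjacency` (sparse
#'   integer-valued matrix, collectors x taxa, dimnames in first-appearance
#'   order) and `resolution`.
#'
#' @examples
#' recs <- tibble::tibble(
#'   record_id = c("r1", "r2"),
#'   collector_ids = list(c("irwin,hs", "ratter,ja"), "irwin,hs"),
#'   taxon_name = c("Myrcia tomentosa", "Myrcia tomentosa"))
#' attr(recs, "resolved") <- TRUE
#' build_scn(recs)
#' @export
build_scn <- function(records, resolution = "species") {
  bad <- lengths(records$collector_ids) == 0 | is_blank(records$taxon_name)
  if (any(bad)) {
    abort(paste0("Records without collector ids or taxon cannot enter the ",
                 "SCN (filter them first): ",
                 paste(head(records$record_id[bad], 10), collapse = ", "),
                 if (sum(bad) > 10) " ..." else ""))
  }
  n_coll <- lengths(records$collector_ids)
  coll <- unlist(records$collector_ids, use.names = FALSE)
  taxa <- rep(trimws(records$taxon_name), n_coll)

  collectors <- unique(coll)
  taxa_set <- unique(taxa)
  A <- sparseMatrix(
    i = match(coll, collectors), j = match(taxa, taxa_set),
    x = 1, dims = c(length(collectors), length(taxa_set)),
    dimnames = list(collectors, taxa_set)
  )
  new_scn(A, resolution)
}

new_scn <- function(biadjacency, resolution) {
  structure(list(biadjacency = biadjacency, resolution = resolution),
            class = "scn")
}

#' @export
print.scn <- function(x, ...) {
  A <- x$biadjacency
  cat("Species-collector network (bipartite)\n")
  cat("  collectors:", nrow(A), " taxa:", ncol(A),
      " edges:", Matrix::nnzero(A), "\n")
  cat("  taxonomic resolution:", x$resolution, "\n")
  invisible(x)
}

#' Species bag of a collector
#'
#' The species bag of collector u_i is row i of the biadjacency matrix:
#' the vector of counts of each taxon that collector recorded.  Its sum is
#' the collector's total record count in the dataset.
#'
#' @param scn An `scn` object.
#' @param collector Collector identifier.
#' @return Named numeric vector of length m (one entry per taxon node).
#' @export
species_bag <- function(scn, collector) {
  stopifnot(inherits(scn, "scn"))
  if (!collector %in% rownames(scn$biadjacency)) {
    abort(paste0("Unknown collector: '", collector, "'"))
  }
  bag <- scn$biadjacency[collector, ]
  setNames(as.numeric(bag), colnames(scn$biadjacency))
}

#' Quorum of a taxon
#'
#' The quorum of taxon v_j is column j of the biadjacency matrix: the
#' vector of counts of records of that taxon by each collector.  Its sum is
#' the number of (record, collector) incidences involving the taxon; on
#' datasets where every record has one collector this equals the taxon's
#' record count.
#'
#' @param scn An `scn` object.
#' @param taxon Taxon node name.
#' @return Named numeric vector of length n (one entry per collector).
#' @export
quorum <- function(scn, taxon) {
  stopifnot(inherits(scn, "scn"))
  if (!taxon %in% colnames(scn$biadjacency)) {
    abort(paste0("Unknown taxon: '", taxon, "'"))
  }
  q <- scn$biadjacency[, taxon]
  setNames(as.numeric(q), rownames(scn$biadjacency))
}

#' Aggregate an SCN to a higher taxonomic rank
#'
#' Taxonomic aggregation collapses taxon nodes into their ancestors at rank
#' T by summing the quorum vectors of all species in each group, producing
#' a new SCN whose taxon nodes are the rank-T groups.  Collector nodes and
#' their row sums are untouched, and the total weight of the biadjacency
#' matrix is conserved.
#'
#' @param scn An `scn` object.
#' @param taxonomy Named character vector mapping every current taxon node
#'   to its group at the target rank (e.g. species -> family).  A
#'   convenient source is [taxonomy_from_records()].
#' @param rank Label of the target rank (becomes the new resolution).
#' @return A new `scn` at the coarser resolution; group columns appear in
#'   first-appearance order of their member taxa.
#' @export
aggregate_scn <- function(scn, taxonomy, rank) {
  stopifnot(inherits(scn, "scn"))
  taxa <- colnames(scn$biadjacency)
  orphans <- setdiff(taxa, names(taxonomy))
  if (length(orphans) > 0) {
    abort(paste0("Taxonomy does not cover ", length(orphans), " taxa: ",
                 paste(head(orphans, 10), collapse = ", "),
                 if (length(orphans) > 10) " ..." else ""))
  }
  groups_per_taxon <- unname(taxonomy[taxa])
  groups <- unique(groups_per_taxon)
  M <- sparseMatrix(i = seq_along(taxa),
                    j = match(groups_per_taxon, groups),
                    x = 1, dims = c(length(taxa), length(groups)),
                    dimnames = list(taxa, groups))
  new_scn(scn$biadjacency %*% M, rank)
}

#' Derive a taxonomy map from occurrence records
#'
#' Reads the species-to-group mapping off the records themselves (e.g. the
#' Darwin Core `family` column), for use with [aggregate_scn()].
#' Conflicting group assignments for one taxon are an error.
#'
#' @param records Occurrence tibble with `taxon_name` and the grouping
#'   column filled.
#' @param group_col Column holding the higher-rank name (default
#'   `"family"`).
#' @return Named character vector: taxon name -> group name.
#' @export
taxonomy_from_records <- function(records, group_col = "family") {
  ok <- !is_blank(records$taxon_name) & !is_blank(records[[group_col]])
  pairs <- unique(tibble(taxon = trimws(records$taxon_name[ok]),
                         group = trimws(records[[group_col]][ok])))
  dup <- unique(pairs$taxon[duplicated(pairs$taxon)])
  if (length(dup) > 0) {
    abort(paste0("Conflicting ", group_col, " assignments for: ",
                 paste(head(dup, 10), collapse = ", ")))
  }
  setNames(pairs$group, pairs$taxon)
}

#' Drop weak edges (and optionally isolated nodes) from an SCN
#'
#' Removes collector-taxon ties whose weight falls below a threshold, the
#' display filter used to expose the backbone of large aggregated networks
#' (e.g. keeping only collector-family ties occurring at least 20 times).
#'
#' @param scn An `scn` object.
#' @param min_weight Minimum edge weight to keep (>= 1).
#' @param drop_isolates Also remove nodes left without any edge.
#' @return The filtered `scn`.
#' @export
filter_scn_edges <- function(scn, min_weight, drop_isolates = FALSE) {
  stopifnot(inherits(scn, "scn"), min_weight >= 1)
  A <- scn$biadjacency
  A@x[A@x < min_weight] <- 0
  A <- Matrix::drop0(A)
  if (drop_isolates) {
    A <- A[rowSums(A) > 0, colSums(A) > 0, drop = FALSE]
  }
  new_scn(A, scn$resolution)
}
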