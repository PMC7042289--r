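#' Extract collecting teams from resolved records
#'
#' A team is the distinct list of collectors authoring one record.  Teams
#' are per-record, not per-event: two records with identical collector
#' lists are two distinct collaboration acts.  Records with no resolved
#' collectors are skipped and reported; single-collector records yield
#' size-1 teams (kept, because the individualist analysis needs them).
#'
#' @param records Resolved occurrence tibble ([resolve_collectors()]).
#' @return A tibble with `record_id`, `members` (list column of collector
#'   ids, already de-duplicated upstream) and `size`; record ids skipped
#'   for lack of collectors are attached as attribute `skipped`.
#' @export
extract_teams <- function(records) {
  has_coll <- lengths(records$collector_ids) > 0
  teams <- tibble(
    record_id = records$record_id[has_coll],
    members = lapply(records$collector_ids[has_coll], unique),
    size = lengths(records$collector_ids[has_coll])
  )
  attr(teams, "skipped") <- records$record_id[!has_coll]
  teams
}

#' Build a collector coworking network (CWN)
#'
#' The CWN is a unipartite weighted graph over collectors in which each
#' record with at least two collectors is a distinct collaboration act
#' tying every pair of its team members.  Two weighting schemes:
#'
#' * `hyperbolic` — each record k contributes 1/(n^(k) - 1) to every pair
#'   of its team, so a two-person record contributes the maximum weight 1
#'   and larger teams dilute individual ties.  Size-1 records are excluded
#'   from the sums (the rule is singular at n = 1) but their collectors
#'   still become (isolated) nodes.
#' * `full_count` — each record contributes 1 to every pair, i.e. the
#'   weight of (i, j) is the number of records on which i and j co-appear.
#'
#' The adjacency matrix is symmetric with a zero diagonal: a collector
#' holds no collaborative tie to itself (guaranteed upstream by per-record
#' de-duplication of ids).
#'
#' @param teams Team tibble from [extract_teams()].
#' @param weighting `"hyperbolic"` (default) or `"full_count"`.
#' @return An object of class `cwn`: a list with `adjacency` (sparse
#'   symmetric matrix over all collectors seen in the input, including
#'   those with no collaborations) and `weighting`.
#'
#' @examples
#' teams <- tibble::tibble(record_id = "r1",
#'                         members = list(c("a,b", "c,d")), size = 2L)
#' build_cwn(teams)
#' @export
build_cwn <- function(teams, weighting = c("hyperbolic", "full_count")) {
  weighting <- tryCatch(match.arg(weighting), error = function(e) {
    abort(paste0("Unknown weighting scheme: '", weighting[1],
                 "' (use \"hyperbolic\" or \"full_count\")."),
          class = "collnet_config_error")
  })
  collectors <- unique(unlist(teams$members, use.names = FALSE))
  n <- length(collectors)

  collab <- teams$members[teams$size >= 2]
  ii <- jj <- integer(0); ww <- numeric(0)
  if (length(collab) > 0) {
    per_team <- lapply(collab, function(m) {
      idx <- match(m, collectors)
      p <- combn(idx, 2)
      w <- if (weighting == "hyperbolic") 1 / (length(m) - 1) else 1
      list(i = p[1, ], j = p[2, ], w = rep(w, ncol(p)))
    })
    ii <- unlist(lapply(per_team, `[[`, "i"))
    jj <- unlist(lapply(per_team, `[[`, "j"))
    ww <- unlist(lapply(per_team, `[[`, "w"))
  }
  # accumulate the upper triangle only and mirror it, so a_ij and a_ji are
  # bit-identical regardless of floating-point summation order
  U <- sparseMatrix(i = pmin(ii, jj), j = pmax(ii, jj), x = ww,
                    dims = c(n, n), dimnames = list(collectors, collectors))
  A <- U + Matrix::t(U)
  structure(list(adjacency = A, weighting = weighting), class = "cwn")
}

#' @export
print.cwn <- function(x, ...) {
  A <- x$adjacency
  cat("Collector coworking network (", x$weighting, " weighting)\n", sep = "")
  cat("  collectors:", nrow(A), " edges:", Matrix::nnzero(A) / 2, "\n")
  cat("  individualists:", length(individualists(x)), "\n")
  invisible(x)
}

#' Individualist collectors
#'
#' Individualists are CWN nodes with degree zero: collectors who never
#' co-authored a record (or whose co-authors were never named).  They carry
#' no structural role in the collaboration network but depress its overall
#' density.
#'
#' @param cwn A `cwn` object.
#' @return Character vector of collector ids with no incident edge.
#' @export
individualists <- function(cwn) {
  stopifnot(inherits(cwn, "cwn"))
  deg <- rowSums(cwn$adjacency != 0)
  rownames(cwn$adjacency)[deg == 0]
}
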