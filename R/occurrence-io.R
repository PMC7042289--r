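#' Read a Darwin Core style occurrence table
#'
#' Reads a delimited text file of species occurrence records into the
#' canonical record tibble used by all model builders.  Columns are located
#' by Darwin Core term names (`recordedBy`, `scientificName`, `taxonRank`,
#' `family`, `eventDate`, `countryCode`, `stateProvince`,
#' `decimalLatitude`, `decimalLongitude`, `issue`), either directly from the
#' header or through `column_map`.  Only `recordedBy` and `scientificName`
#' are mandatory; every other field is optional and absent columns simply
#' yield missing values.  No rows are dropped at this stage: filtering is a
#' separate, explicit step ([filter_records()]), so that the species-collector
#' and coworking models can apply different requirements to one shared read.
#'
#' Dates and coordinates are parsed leniently (kept as text / best-effort
#' numeric) and never cause a record to be rejected; neither model uses them.
#'
#' @param path Path to a delimited UTF-8 text file with a header row.
#' @param column_map Named character vector mapping Darwin Core terms to
#'   column names in the file, e.g. `c(recordedBy = "collectors")`.  Terms
#'   not mentioned are looked up under their own name.  An optional
#'   `record_id` entry names a column holding stable record identifiers;
#'   otherwise identifiers `rec000001, ...` are assigned by row order.
#' @param delim Field delimiter.  `NULL` (default) auto-detects tab versus
#'   comma from the header line.
#'
#' @return A tibble with one row per data row (order preserved) and columns
#'   `record_id`, `recorded_by_raw`, `collector_ids` (list column, empty
#'   until [resolve_collectors()] runs), `taxon_name`, `taxon_rank`,
#'   `family`, `event_date`, `country_code`, `state_province`,
#'   `decimal_latitude`, `decimal_longitude`, `issues`.  A read report
#'   (rows read, rows with blank mandatory fields) is attached as an
#'   attribute and retrievable with [read_report()].
#'
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("recordedBy\tscientificName",
#'              "Irwin, H.S.; Ratter, J.A.\tMyrcia tomentosa"), f)
#' occ <- read_occurrences(f)
#' read_report(occ)
#' @export
read_occurrences <- function(path, column_map = NULL, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Cannot read occurrence file: '", path, "' does not exist."))
  }
  header_line <- readLines(path, n = 1L, encoding = "UTF-8")
  if (is.null(delim)) {
    delim <- if (grepl("\t", header_line)) "\t" else ","
  }
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, na = character(), progress = FALSE,
    show_col_types = FALSE
  )

  cmap <- setNames(names(dwc_terms), names(dwc_terms))
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), c(names(dwc_terms), "record_id"))
    if (length(bad) > 0) {
      abort(paste0("Unknown Darwin Core term(s) in column_map: ",
                   paste(bad, collapse = ", ")))
    }
    cmap[names(column_map)] <- unname(column_map)
  }
  for (term in c("recordedBy", "scientificName")) {
    if (!cmap[[term]] %in% names(raw)) {
      abort(paste0("Mandatory column for Darwin Core term '", term,
                   "' (expected header '", cmap[[term]],
                   "') is absent from the file."),
            class = "collnet_config_error")
    }
  }

  pick <- function(term) {
    col <- cmap[[term]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }

  if (!is.null(column_map) && "record_id" %in% names(column_map) &&
      column_map[["record_id"]] %in% names(raw)) {
    ids <- raw[[column_map[["record_id"]]]]
    if (anyDuplicated(ids)) abort("record_id column contains duplicates.")
  } else {
    ids <- sprintf("rec%06d", seq_len(nrow(raw)))
  }

  records <- tibble(
    record_id         = ids,
    recorded_by_raw   = pick("recordedBy"),
    collector_ids     = rep(list(character(0)), nrow(raw)),
    taxon_name        = pick("scientificName"),
    taxon_rank        = pick("taxonRank"),
    family            = pick("family"),
    event_date        = pick("eventDate"),
    country_code      = pick("countryCode"),
    state_province    = pick("stateProvince"),
    decimal_latitude  = suppressWarnings(as.numeric(pick("decimalLatitude"))),
    decimal_longitude = suppressWarnings(as.numeric(pick("decimalLongitude"))),
    issues            = pick("issue")
  )

  attr(records, "read_report") <- list(
    rows_read            = nrow(records),
    empty_recorded_by    = sum(is_blank(records$recorded_by_raw)),
    empty_scientific_name = sum(is_blank(records$taxon_name))
  )
  attr(records, "resolved") <- FALSE
  records
}

#' Retrieve the read report attached to an occurrence tibble
#'
#' @param records A tibble returned by [read_occurrences()].
#' @return A list with `rows_read`, `empty_recorded_by`,
#'   `empty_scientific_name`.
#' @export
read_report <- function(records) {
  attr(records, "read_report")
}

#' Record filter configuration
#'
#' The two network models need different record subsets: the
#' species-collector network needs a collector *and* a taxon at a single
#' rank, while the coworking network only needs collectors.  A filter
#' configuration captures one such requirement set.
#'
#' @param require_collectors Drop records with no collectors (blank
#'   `recordedBy` before resolution; empty `collector_ids` after).
#' @param require_taxon Drop records with a blank `scientificName`.
#' @param allowed_ranks Character vector of acceptable `taxonRank` labels
#'   (matched case-insensitively), or `NULL` to disable rank filtering.
#' @param drop_issue_patterns Character vector of substrings; a record whose
#'   `issue` field contains any of them is dropped.  Empty by default: no
#'   issue value is treated as disqualifying unless the user says so.
#' @return An object of class `record_filter_config`.
#' @export
record_filter_config <- function(require_collectors = TRUE,
                                 require_taxon = TRUE,
                                 allowed_ranks = NULL,
                                 drop_issue_patterns = character(0)) {
  if (!is.null(allowed_ranks) && length(allowed_ranks) == 0) {
    abort("allowed_ranks must be NULL (disabled) or a nonempty character vector.")
  }
  structure(
    list(require_collectors = isTRUE(require_collectors),
         require_taxon = isTRUE(require_taxon),
         allowed_ranks = allowed_ranks,
         drop_issue_patterns = drop_issue_patterns),
    class = "record_filter_config"
  )
}

#' Filter occurrence records for model building
#'
#' Partitions records into those kept and those dropped, with exactly one
#' primary drop reason per dropped record (reasons are checked in the order
#' `no-collectors`, `no-taxon`, `rank-not-allowed`, `issue-flagged`).  With
#' all filters disabled the input passes through unchanged, and filtering
#' the kept set again never drops anything.
#'
#' @param records Occurrence tibble from [read_occurrences()] (optionally
#'   resolved by [resolve_collectors()]).
#' @param cfg A [record_filter_config()].
#' @return A list with `kept` (tibble, attributes preserved) and `dropped`
#'   (tibble with `record_id`, `reason`).
#' @export
filter_records <- function(records, cfg = record_filter_config()) {
  stopifnot(inherits(cfg, "record_filter_config"))
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  if (cfg$require_collectors) {
    no_coll <- if (isTRUE(attr(records, "resolved"))) {
      lengths(records$collector_ids) == 0
    } else {
      is_blank(records$recorded_by_raw)
    }
    reason[is.na(reason) & no_coll] <- "no-collectors"
  }
  if (cfg$require_taxon) {
    reason[is.na(reason) & is_blank(records$taxon_name)] <- "no-taxon"
  }
  if (!is.null(cfg$allowed_ranks)) {
    ok_rank <- tolower(trimws(records$taxon_rank)) %in% tolower(cfg$allowed_ranks)
    reason[is.na(reason) & !ok_rank] <- "rank-not-allowed"
  }
  if (length(cfg$drop_issue_patterns) > 0) {
    hit <- Reduce(`|`, lapply(cfg$drop_issue_patterns, function(p) {
      !is.na(records$issues) & grepl(p, records$issues, fixed = TRUE)
    }), init = rep(FALSE, n))
    reason[is.na(reason) & hit] <- "issue-flagged"
  }

  kept <- records[is.na(reason), , drop = FALSE]
  attr(kept, "read_report") <- attr(records, "read_report")
  attr(kept, "resolved") <- attr(records, "resolved")
  list(
    kept = kept,
    dropped = tibble(record_id = records$record_id[!is.na(reason)],
                     reason = reason[!is.na(reason)])
  )
}

#' Write occurrence records back to a Darwin Core style table
#'
#' Inverse of [read_occurrences()]: emits a delimited table under Darwin
#' Core header names so that a read/write/read round trip preserves all
#' mandatory fields verbatim.  Resolved collector ids, if present, are
#' written pipe-separated in an extra `collectorIds` column.
#'
#' @param records Occurrence tibble.
#' @param path Output file path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(records, path, delim = "\t") {
  out <- tibble(
    recordID         = records$record_id,
    recordedBy       = records$recorded_by_raw,
    scientificName   = records$taxon_name,
    taxonRank        = records$taxon_rank,
    family           = records$family,
    eventDate        = records$event_date,
    countryCode      = records$country_code,
    stateProvince    = records$state_province,
    decimalLatitude  = records$decimal_latitude,
    decimalLongitude = records$decimal_longitude,
    issue            = records$issues,
    collectorIds     = vapply(records$collector_ids, paste, "", collapse = "|")
  )
  readr::write_delim(out, path, delim = delim, na = "", progress = FALSE)
  invisible(path)
}
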