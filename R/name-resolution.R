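#' Default between-name delimiters for recordedBy strings
#'
#' Herbarium tables separate multiple collectors with wildly inconsistent
#' punctuation.  The default inventory splits on semicolon, pipe, ampersand
#' and the connectives " e " / " and "; the bare comma is deliberately *not*
#' a between-name delimiter because the dominant "Surname, Initials" layout
#' makes it ambiguous.
#'
#' @return Character vector of literal delimiter strings, in match order.
#' @export
default_delimiters <- function() {
  c(";", "|", "&", " e ", " and ")
}

#' Default stop-list of non-name tokens
#'
#' Tokens that occur in collector fields but denote no person: "s.n."
#' (sine nomine), question marks, determiner placeholders.  Compared against
#' the letters-only lowercase form of a token.
#'
#' @return Character vector of stop tokens.
#' @export
default_stoplist <- function() {
  c("sn", "ilegivel", "indet", "anon", "anonymous", "unknown", "collector")
}

et_al_regex <- "(?i)\\bet\\.?[[:space:]]*al[.,]*(?=([[:space:];,&|]|$))"

#' Split raw recordedBy strings into atomized collector names
#'
#' Splits each string on the configured delimiters, trims whitespace and
#' leading/trailing commas, and drops empty fragments, preserving original
#' order.  "et al."-type markers (which aggregate unnamed secondary
#' collectors) are removed from the name list and flagged: they denote the
#' *absence* of named co-collectors and must not become nodes.
#'
#' @param x Character vector of raw `recordedBy` strings.
#' @param delimiters Ordered character vector of literal separator strings;
#'   see [default_delimiters()].
#' @return A list with one character vector of raw names per input string,
#'   with a logical attribute `et_al` marking inputs that carried an
#'   "et al." expression.
#'
#' @examples
#' atomize("Irwin, H.S.; Ratter, J.A.")
#' atomize("Silva, M. et al.")
#' @export
atomize <- function(x, delimiters = default_delimiters()) {
  if (length(delimiters) == 0) abort("delimiters must be nonempty.")
  x <- as.character(x)
  x[is.na(x)] <- ""

  et_al <- stringr::str_detect(x, et_al_regex)
  x <- stringr::str_remove_all(x, et_al_regex)

  split_re <- paste0("(", paste(vapply(delimiters, escape_regex, ""),
                                collapse = "|"), ")")
  parts <- stringr::str_split(x, split_re)
  out <- lapply(parts, function(p) {
    p <- stringr::str_trim(p)
    p <- stringr::str_remove_all(p, "^[,[:space:]]+|[,[:space:]]+$")
    p[nzchar(p) & stringr::str_detect(p, "[[:alpha:]]")]
  })
  attr(out, "et_al") <- et_al
  out
}

escape_regex <- function(s) {
  gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", s)
}

#' Normalize an atomized collector name to its identifier token
#'
#' Maps a personal name to the canonical lowercase `"surname,initials"`
#' token used as the collector identifier, e.g. both `"Proença, C.E.B."`
#' and `"c. e. b. proenca"` become `"proenca,ceb"`.  The rule: transliterate
#' diacritics to ASCII, lowercase, locate surname and given parts from
#' either a `"Surname, Given"` layout (comma present) or a
#' `"Given Surname"` layout (no comma; last word is the surname), strip all
#' non-letters from the surname, and concatenate the first letter of every
#' given-name chunk as the initials.  The function is deterministic and
#' idempotent on its own output.
#'
#' Tokens with fewer than two letters, purely numeric tokens, stop-list
#' entries, and names from which no surname or no initials can be formed
#' are rejected: the returned element is `NA` and a parallel `reason`
#' attribute says why.
#'
#' @param x Character vector of atomized raw names.
#' @param stoplist Character vector of letters-only tokens to reject; see
#'   [default_stoplist()].
#' @return Character vector of identifier tokens (`NA` where rejected) with
#'   a character attribute `reason` (`NA` where accepted).
#'
#' @examples
#' normalize_collector(c("Proença, C.E.B.", "howard s. irwin", "123"))
#' @export
normalize_collector <- function(x, stoplist = default_stoplist()) {
  out <- character(length(x))
  reason <- rep(NA_character_, length(x))

  for (i in seq_along(x)) {
    nm <- x[[i]]
    if (is.na(nm) || !nzchar(trimws(nm))) {
      out[i] <- NA_character_; reason[i] <- "blank"; next
    }
    ascii <- suppressWarnings(iconv(nm, from = "UTF-8", to = "ASCII//TRANSLIT"))
    if (is.na(ascii)) ascii <- iconv(nm, from = "UTF-8", to = "ASCII", sub = "")
    ascii <- tolower(ascii)
    # transliteration artefacts (M"uller, L'odz) and stray punctuation
    ascii <- gsub("[\"'`^~]", "", ascii)

    letters_only <- gsub("[^a-z]", "", ascii)
    if (!nzchar(letters_only)) {
      out[i] <- NA_character_; reason[i] <- "no alphabetic content"; next
    }
    if (nchar(letters_only) < 2) {
      out[i] <- NA_character_; reason[i] <- "fewer than 2 letters"; next
    }
    if (letters_only %in% stoplist) {
      out[i] <- NA_character_; reason[i] <- "stop-list token"; next
    }
    # already a canonical token ("surname,initials"): pass through, which
    # makes normalization idempotent on its own output
    if (grepl("^[a-z]+,[a-z]+$", nm)) {
      out[i] <- nm; next
    }

    if (grepl(",", ascii, fixed = TRUE)) {
      surname_part <- sub(",.*$", "", ascii)
      given_part <- sub("^[^,]*,", "", ascii)
    } else {
      words <- strsplit(trimws(ascii), "[[:space:]]+")[[1]]
      if (length(words) < 2) {
        out[i] <- NA_character_; reason[i] <- "no initials"; next
      }
      surname_part <- words[length(words)]
      given_part <- paste(words[-length(words)], collapse = " ")
    }

    surname <- gsub("[^a-z]", "", surname_part)
    # given-name chunks: words, dotted initials, hyphenated parts each
    # contribute their first letter
    chunks <- strsplit(given_part, "[[:space:].\\-]+")[[1]]
    chunks <- chunks[nzchar(gsub("[^a-z]", "", chunks))]
    initials <- paste(substr(gsub("[^a-z]", "", chunks), 1, 1), collapse = "")

    if (!nzchar(surname)) {
      out[i] <- NA_character_; reason[i] <- "no surname"; next
    }
    if (!nzchar(initials)) {
      out[i] <- NA_character_; reason[i] <- "no initials"; next
    }
    out[i] <- paste0(surname, ",", initials)
  }
  attr(out, "reason") <- reason
  out
}

#' Load a collector name map from a two-column delimited file
#'
#' The name map carries the dataset-specific knowledge that several
#' normalized tokens denote one person (name variants, dropped initials,
#' misspellings).  The file has two columns, variant token and canonical
#' identifier, with or without a header.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter (default tab; comma detected from content).
#' @return A named character vector: `names()` are variant tokens, values
#'   canonical identifiers.  Canonical identifiers always map to
#'   themselves.
#' @export
read_name_map <- function(path, delim = NULL) {
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  if (is.null(delim)) delim <- if (grepl("\t", first)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           col_names = c("variant", "canonical"), progress = FALSE,
                           show_col_types = FALSE)
  if (identical(tolower(tab$variant[1]), "variant")) tab <- tab[-1, ]
  as_name_map(setNames(tab$canonical, tab$variant))
}

as_name_map <- function(map) {
  if (is.null(map)) return(setNames(character(0), character(0)))
  dup <- unique(names(map)[duplicated(names(map))])
  conflicting <- dup[vapply(dup, function(v) {
    length(unique(map[names(map) == v])) > 1
  }, logical(1))]
  if (length(conflicting) > 0) {
    abort(paste0("Name map is not functional; variant(s) with multiple ",
                 "canonical ids: ", paste(conflicting, collapse = ", ")),
          class = "collnet_config_error")
  }
  map <- map[!duplicated(names(map))]
  # canonical ids map to themselves
  self <- setdiff(unname(map), names(map))
  c(map, setNames(self, self))
}

#' Resolve raw recordedBy strings into collector identifier lists
#'
#' Runs the full name-cleaning chain over a set of occurrence records:
#' atomize each `recordedBy` string, normalize every fragment to an
#' identifier token, reject non-name tokens, substitute canonical
#' identifiers through the name map, and de-duplicate within each record
#' while preserving first-appearance order.  De-duplication is what later
#' guarantees the coworking network has a zero diagonal: a name repeated on
#' one record is one collector, not a self-collaboration.
#'
#' Records whose identifier list comes out empty (e.g. a bare "et al.") are
#' kept and flagged in the report, never silently removed.
#'
#' @param records Occurrence tibble from [read_occurrences()].
#' @param name_map Named character vector (variant token -> canonical id),
#'   e.g. from [read_name_map()]; `NULL` for the identity map.
#' @param delimiters Passed to [atomize()].
#' @param stoplist Passed to [normalize_collector()].
#' @return The records tibble with `collector_ids` filled, carrying an
#'   `atomization_report` attribute (see [atomization_report()]) with
#'   `records_processed`, `names_extracted`, `et_al_flags`,
#'   `rejected_tokens` (tibble: record_id, token, reason) and
#'   `empty_after_resolution` (record ids).
#' @export
resolve_collectors <- function(records, name_map = NULL,
                               delimiters = default_delimiters(),
                               stoplist = default_stoplist()) {
  map <- as_name_map(name_map)
  frags <- atomize(records$recorded_by_raw, delimiters)
  et_al <- attr(frags, "et_al")

  rejected <- list()
  names_extracted <- 0L
  ids <- vector("list", nrow(records))
  for (i in seq_along(frags)) {
    raw <- frags[[i]]
    names_extracted <- names_extracted + length(raw)
    tok <- normalize_collector(raw, stoplist)
    reasons <- attr(tok, "reason")
    bad <- is.na(tok)
    if (any(bad)) {
      rejected[[length(rejected) + 1L]] <- tibble(
        record_id = records$record_id[i], token = raw[bad],
        reason = reasons[bad])
    }
    tok <- tok[!bad]
    hit <- tok %in% names(map)
    tok[hit] <- unname(map[tok[hit]])
    ids[[i]] <- unique(tok)
  }
  records$collector_ids <- ids
  attr(records, "resolved") <- TRUE
  attr(records, "atomization_report") <- list(
    records_processed = nrow(records),
    names_extracted = names_extracted,
    et_al_flags = sum(et_al),
    rejected_tokens = if (length(rejected)) dplyr::bind_rows(rejected)
                      else tibble(record_id = character(0),
                                  token = character(0),
                                  reason = character(0)),
    empty_after_resolution = records$record_id[lengths(ids) == 0]
  )
  records
}

#' Retrieve the atomization report attached by resolve_collectors()
#'
#' @param records A resolved occurrence tibble.
#' @return The report list.
#' @export
atomization_report <- function(records) {
  attr(records, "atomization_report")
}
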