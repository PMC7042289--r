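# Fixture builders shared across test files.

# A resolved-record tibble straight from collector-id lists and taxa,
# bypassing name resolution.
toy_records <- function(collector_lists, taxa = NULL, ranks = "species",
                        families = NULL) {
  n <- length(collector_lists)
  recs <- tibble::tibble(
    record_id = sprintf("r%03d", seq_len(n)),
    recorded_by_raw = vapply(collector_lists, paste, "", collapse = "; "),
    collector_ids = lapply(collector_lists, unique),
    taxon_name = taxa %||% rep("Genus sp", n),
    taxon_rank = rep_len(ranks, n),
    family = families %||% rep(NA_character_, n),
    event_date = NA_character_, country_code = NA_character_,
    state_province = NA_character_, decimal_latitude = NA_real_,
    decimal_longitude = NA_real_, issues = NA_character_
  )
  attr(recs, "resolved") <- TRUE
  recs
}

# Random resolved records over small collector/taxon pools.
random_records <- function(n_records, n_collectors = 8, n_taxa = 6,
                           max_team = 4) {
  pool <- sprintf("coll%02d,x", seq_len(n_collectors))
  taxa <- sprintf("Taxon %02d", sample(n_taxa, n_records, replace = TRUE))
  teams <- lapply(seq_len(n_records), function(i) {
    sample(pool, sample(max_team, 1))
  })
  toy_records(teams, taxa)
}

# Team tibble straight from generator ground truth.
extract_teams_from_truth <- function(d) {
  tibble::tibble(record_id = d$truth$records$record_id,
                 members = d$truth$records$team,
                 size = d$truth$records$team_size)
}

# Random named undirected igraph for analytics oracle checks.
random_named_graph <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

graph_edge_ends <- function(g) {
  el <- igraph::as_edgelist(g)
  list(from = el[, 1], to = el[, 2])
}
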