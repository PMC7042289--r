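#' Configuration for the synthetic occurrence-data generator
#'
#' The generator emulates the structure of a real herbarium occurrence
#' table: multi-collector `recordedBy` strings with heterogeneous
#' delimiters and name variants, species names with family mappings,
#' heavily skewed per-collector record counts (a few hub collectors
#' account for a large share of records), a log-decaying team-size
#' distribution, a sizeable fraction of individualist collectors who only
#' ever record alone, and planted taxonomic-interest communities whose
#' members both co-collect and share family preferences.
#'
#' Defaults reproduce the conditions observed in large herbarium datasets:
#' a truncated-geometric team-size law (mean 1.73, so record counts fall
#' off log-linearly with team size) and an individualist share of 39.5%.
#'
#' @param n_collectors Number of collectors.
#' @param n_species Number of species (each mapped to a family).
#' @param n_families Number of families, partitioned evenly among the
#'   interest communities.
#' @param n_records Number of occurrence records to emit.
#' @param n_communities Number of planted interest/coworking communities.
#' @param concentration Probability that a record's species is drawn from
#'   the preferred family of a (uniformly chosen) team member rather than
#'   uniformly from all species.
#' @param team_affinity Probability that each co-collector of a
#'   collaborative record is drawn from the lead collector's community
#'   rather than from all collaborative collectors.
#' @param team_size_probs Probability vector over team sizes 1, 2, ...;
#'   the default is a geometric law truncated at 8 with success
#'   probability 1/1.73 (mean team size 1.73).
#' @param individualist_fraction Fraction of collectors planted as
#'   individualists: they appear only on single-collector records.
#' @param propensity_sdlog Log-sd of the lognormal record propensities
#'   that skew per-collector record counts (hub collectors emerge).
#' @param name_noise List with elements `variant` (probability that a
#'   collector's name is written as a known variant, e.g. a dropped final
#'   initial or a reordered layout), `et_al` (probability that a
#'   collaborative record names only its first collector plus "et al."),
#'   and `delimiter_probs` (named probability vector over between-name
#'   delimiter strings).
#' @param seed Integer seed; the full output is reproducible per seed.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_collectors = 200,
                             n_species = 400,
                             n_families = 20,
                             n_records = 2000,
                             n_communities = 4,
                             concentration = 0.9,
                             team_affinity = 0.9,
                             team_size_probs = default_team_size_probs(),
                             individualist_fraction = 0.395,
                             propensity_sdlog = 1,
                             name_noise = list(
                               variant = 0.05,
                               et_al = 0.03,
                               delimiter_probs = c(";" = 0.7, "|" = 0.1,
                                                   "&" = 0.1, " e " = 0.1)),
                             seed = 1L) {
  cfg <- list(n_collectors = n_collectors, n_species = n_species,
              n_families = n_families, n_records = n_records,
              n_communities = n_communities, concentration = concentration,
              team_affinity = team_affinity,
              team_size_probs = team_size_probs / sum(team_size_probs),
              individualist_fraction = individualist_fraction,
              propensity_sdlog = propensity_sdlog,
              name_noise = name_noise, seed = as.integer(seed))
  counts <- c(n_collectors, n_species, n_families, n_records, n_communities)
  if (any(counts < 1)) abort("All generator counts must be >= 1.")
  probs <- c(concentration, team_affinity, individualist_fraction,
             name_noise$variant, name_noise$et_al)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  if (any(cfg$team_size_probs < 0)) abort("team_size_probs must be nonnegative.")
  if (n_families < n_communities) {
    abort("Need at least one family per community.")
  }
  max_size <- max(which(cfg$team_size_probs > 0))
  n_collab <- n_collectors - round(individualist_fraction * n_collectors)
  if (max_size >= 2 && sum(cfg$team_size_probs[-1]) > 0 && n_collab < max_size) {
    abort(paste0("Infeasible config: largest team size ", max_size,
                 " exceeds the ", n_collab, " collaborative collectors."))
  }
  structure(cfg, class = "generator_config")
}

#' Default log-decaying team-size distribution
#'
#' Truncated geometric over sizes 1..8 with success probability 1/1.73,
#' giving a mean team size of about 1.73 and record counts that decay
#' log-linearly with team size.
#'
#' @return Probability vector over team sizes 1..8.
#' @export
default_team_size_probs <- function() {
  p <- stats::dgeom(0:7, prob = 1 / 1.73)
  p / sum(p)
}

# Deterministic pool of unique pronounceable surnames; a share carries
# diacritics so normalization is exercised.
make_surnames <- function(n) {
  syll <- c("sil", "va", "mo", "ra", "per", "ei", "ro", "lan", "de", "car",
            "do", "so", "men", "tes", "ba", "li", "ma", "cha", "ve", "ga")
  pool <- character(0)
  k <- 2L
  while (length(pool) < n) {
    combos <- apply(expand.grid(rep(list(syll), k)), 1, paste, collapse = "")
    pool <- unique(c(pool, combos))
    k <- k + 1L
  }
  s <- pool[seq_len(n)]
  # sprinkle diacritics on the display forms (ids stay ASCII)
  disp <- s
  third <- seq_len(n) %% 7 == 0
  disp[third] <- sub("a", "á", disp[third])
  fifth <- seq_len(n) %% 11 == 0
  disp[fifth] <- sub("e", "é", disp[fifth])
  list(id = s, display = paste0(toupper(substr(disp, 1, 1)),
                                substr(disp, 2, nchar(disp))))
}

format_initials <- function(ini) {
  paste0(paste(toupper(strsplit(ini, "")[[1]]), collapse = "."), ".")
}

#' Generate a synthetic occurrence dataset with known ground truth
#'
#' Emits a Darwin Core style occurrence tibble (same dialect as
#' [read_occurrences()] expects) plus the ground truth needed to test
#' every downstream model: canonical collector ids per record, planted
#' community and preferred-family labels, true team sizes, the realized
#' individualist set, the species-to-family taxonomy, and the name map
#' that resolves all emitted name variants.
#'
#' Mechanics: every collector belongs to one interest community and has
#' one preferred family from that community's family block.  For each
#' record, a team size is drawn from the configured distribution; a lead
#' collector is drawn proportionally to lognormal propensities
#' (individualists can only lead size-1 records); co-collectors come from
#' the lead's community with probability `team_affinity`.  The species is
#' drawn from the preferred family of a uniformly chosen team member with
#' probability `concentration`, otherwise uniformly, so a collector's
#' dominant recorded family tracks their planted preference regardless of
#' how often they lead.  Name noise then corrupts the `recordedBy` string
#' exactly the way real tables are corrupted: variant spellings, mixed
#' delimiters, and "et al." truncation (which hides true team members from
#' any parser — that information loss is deliberate and is reflected in
#' the ground truth as `observable_team`).
#'
#' @param config A [generator_config()].
#' @return A list with `occurrences` (tibble with columns `recordedBy`,
#'   `scientificName`, `taxonRank`, `family`, `eventDate`, `countryCode`,
#'   `stateProvince`, `decimalLatitude`, `decimalLongitude`, `issue`) and
#'   `truth`, a list with `collectors` (tibble: collector_id, display_name,
#'   community, preferred_family, planted_individualist), `records`
#'   (tibble: record_id, team, observable_team (list columns), team_size,
#'   species, family), `species_families` (named vector),
#'   `name_map` (variant token -> canonical id), and `individualists`
#'   (realized: collectors never on a collaborative record).
#' @export
generate_occurrences <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_occurrences_impl(config))
}

generate_occurrences_impl <- function(cfg) {
  n <- cfg$n_collectors
  nm <- make_surnames(n)
  n_initials <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.5, 0.2))
  initials <- vapply(n_initials, function(k) {
    paste(sample(letters, k, replace = TRUE), collapse = "")
  }, "")
  collector_id <- paste0(nm$id, ",", initials)
  display <- paste0(nm$display, ", ",
                    vapply(initials, format_initials, ""))

  community <- sample(rep_len(seq_len(cfg$n_communities), n))
  fam_block <- split(seq_len(cfg$n_families),
                     rep_len(seq_len(cfg$n_communities), cfg$n_families))
  family_names <- sprintf("Family%02d", seq_len(cfg$n_families))
  preferred_family <- vapply(community, function(cm) {
    fb <- fam_block[[cm]]
    family_names[fb[sample.int(length(fb), 1)]]
  }, "")

  n_indiv <- round(cfg$individualist_fraction * n)
  planted_indiv <- rep(FALSE, n)
  planted_indiv[sample(n, n_indiv)] <- TRUE
  propensity <- stats::rlnorm(n, 0, cfg$propensity_sdlog)

  species_family_idx <- rep_len(seq_len(cfg$n_families), cfg$n_species)
  species_names <- sprintf("Genus%03d epithetum%03d",
                           species_family_idx, seq_len(cfg$n_species))
  species_families <- setNames(family_names[species_family_idx], species_names)
  species_by_family <- split(seq_len(cfg$n_species),
                             family_names[species_family_idx])

  collab_pool <- which(!planted_indiv)
  community_pool <- lapply(seq_len(cfg$n_communities), function(cm) {
    intersect(collab_pool, which(community == cm))
  })

  # variant display forms and the name map that undoes them
  variant_display <- rep(NA_character_, n)
  variant_token <- rep(NA_character_, n)
  multi <- nchar(initials) >= 2
  variant_display[multi] <- paste0(
    nm$display[multi], ", ",
    vapply(substr(initials[multi], 1, nchar(initials[multi]) - 1),
           format_initials, ""))
  variant_token[multi] <- paste0(
    nm$id[multi], ",", substr(initials[multi], 1, nchar(initials[multi]) - 1))
  # single-initial collectors get a layout variant instead (same token)
  variant_display[!multi] <- paste0(vapply(initials[!multi], format_initials, ""),
                                    " ", nm$display[!multi])
  variant_token[!multi] <- collector_id[!multi]
  keep <- variant_token != collector_id & !variant_token %in% collector_id
  name_map <- setNames(collector_id[keep], variant_token[keep])

  sizes <- sample(seq_along(cfg$team_size_probs), cfg$n_records,
                  replace = TRUE, prob = cfg$team_size_probs)
  delim_probs <- cfg$name_noise$delimiter_probs
  delims <- sample(names(delim_probs), cfg$n_records, replace = TRUE,
                   prob = delim_probs)

  team_list <- vector("list", cfg$n_records)
  obs_list <- vector("list", cfg$n_records)
  recorded_by <- character(cfg$n_records)
  species_idx <- integer(cfg$n_records)

  for (k in seq_len(cfg$n_records)) {
    size <- sizes[k]
    if (size == 1L) {
      team <- sample(n, 1, prob = propensity)
    } else {
      lead <- collab_pool[sample(length(collab_pool), 1,
                                 prob = propensity[collab_pool])]
      mates <- integer(0)
      pool_cm <- setdiff(community_pool[[community[lead]]], lead)
      pool_any <- setdiff(collab_pool, lead)
      for (s in seq_len(size - 1L)) {
        from_cm <- stats::runif(1) < cfg$team_affinity
        pool <- if (from_cm) setdiff(pool_cm, mates) else setdiff(pool_any, mates)
        if (length(pool) == 0) pool <- setdiff(pool_any, mates)
        if (length(pool) == 0) break
        mates <- c(mates, pool[sample.int(length(pool), 1)])
      }
      team <- c(lead, mates)
    }
    team_list[[k]] <- collector_id[team]

    # species follows a uniformly chosen team member's preferred family
    if (stats::runif(1) < cfg$concentration) {
      fam <- preferred_family[team[sample.int(length(team), 1)]]
      species_idx[k] <- species_by_family[[fam]][
        sample.int(length(species_by_family[[fam]]), 1)]
    } else {
      species_idx[k] <- sample.int(cfg$n_species, 1)
    }

    use_variant <- stats::runif(length(team)) < cfg$name_noise$variant
    shown <- ifelse(use_variant, variant_display[team], display[team])
    if (length(team) >= 2 && stats::runif(1) < cfg$name_noise$et_al) {
      obs_list[[k]] <- collector_id[team[1]]
      recorded_by[k] <- paste0(shown[1], " et al.")
    } else {
      obs_list[[k]] <- collector_id[team]
      recorded_by[k] <- paste(shown, collapse = paste0(delims[k],
        if (delims[k] %in% c(";", "|", "&")) " " else ""))
    }
  }

  occurrences <- tibble(
    recordedBy = recorded_by,
    scientificName = species_names[species_idx],
    taxonRank = "species",
    family = unname(species_families[species_names[species_idx]]),
    eventDate = sprintf("%04d-%02d-%02d",
                        sample(1960:2017, cfg$n_records, replace = TRUE),
                        sample(1:12, cfg$n_records, replace = TRUE),
                        sample(1:28, cfg$n_records, replace = TRUE)),
    countryCode = "BR",
    stateProvince = "Distrito Federal",
    decimalLatitude = round(stats::runif(cfg$n_records, -16.1, -15.5), 5),
    decimalLongitude = round(stats::runif(cfg$n_records, -48.3, -47.3), 5),
    issue = ""
  )

  seen <- unique(unlist(team_list))
  on_collab <- unique(unlist(team_list[lengths(team_list) >= 2]))
  truth <- list(
    collectors = tibble(collector_id = collector_id,
                        display_name = display,
                        community = community,
                        preferred_family = preferred_family,
                        planted_individualist = planted_indiv),
    records = tibble(record_id = sprintf("rec%06d", seq_len(cfg$n_records)),
                     team = team_list,
                     observable_team = obs_list,
                     team_size = lengths(team_list),
                     species = species_names[species_idx],
                     family = unname(species_families[species_names[species_idx]])),
    species_families = species_families,
    name_map = name_map,
    individualists = setdiff(seen, on_collab)
  )
  list(occurrences = occurrences, truth = truth)
}

#' Write a generated dataset to disk
#'
#' Writes the occurrence table as a tab-separated Darwin Core style file
#' and the ground truth as sidecar delimited files (collector table, name
#' map, species-family taxonomy), so a generated dataset can be fed back
#' through the command-line pipeline.
#'
#' @param dataset Output of [generate_occurrences()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    occurrences = file.path(dir, "occurrences.tsv"),
    collectors = file.path(dir, "collectors_truth.tsv"),
    name_map = file.path(dir, "name_map.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv")
  )
  readr::write_tsv(dataset$occurrences, paths[["occurrences"]], progress = FALSE)
  readr::write_tsv(dataset$truth$collectors, paths[["collectors"]], progress = FALSE)
  readr::write_tsv(tibble(variant = names(dataset$truth$name_map),
                          canonical = unname(dataset$truth$name_map)),
                   paths[["name_map"]], progress = FALSE)
  readr::write_tsv(tibble(taxon = names(dataset$truth$species_families),
                          group = unname(dataset$truth$species_families)),
                   paths[["taxonomy"]], progress = FALSE)
  invisible(paths)
}

#' Agreement between a detected partition and ground-truth labels
#'
#' Label-permutation-invariant agreement: detected communities and true
#' groups are matched one-to-one greedily by descending overlap, and the
#' score is the fraction of nodes whose detected community maps to their
#' true group.  1 means perfect recovery up to relabeling; with two
#' equal-sized true groups, random labels score about 0.5.
#'
#' @param partition A `community_partition` from [detect_communities()],
#'   or a named vector of labels.
#' @param truth Named vector of ground-truth labels over the same node set.
#' @return A number in [0, 1].
#' @export
ground_truth_eval <- function(partition, truth) {
  labels <- if (inherits(partition, "community_partition")) {
    partition$assignment
  } else {
    partition
  }
  if (!setequal(names(labels), names(truth))) {
    abort("partition and truth must cover the same node set.")
  }
  truth <- truth[names(labels)]
  conf <- table(detected = as.character(labels), truth = as.character(truth))
  matched <- 0
  repeat {
    if (nrow(conf) == 0 || ncol(conf) == 0 || max(conf) == 0) break
    idx <- which(conf == max(conf), arr.ind = TRUE)[1, , drop = TRUE]
    matched <- matched + conf[idx[1], idx[2]]
    conf <- conf[-idx[1], -idx[2], drop = FALSE]
  }
  as.numeric(matched / length(labels))
}
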