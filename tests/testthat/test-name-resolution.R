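test_that("atomization splits on configured delimiters and flags et al.", {
  expect_equal(atomize("Irwin, H.S.; Ratter, J.A.")[[1]],
               c("Irwin, H.S.", "Ratter, J.A."))
  expect_equal(atomize("A, B | C, D & E, F")[[1]],
               c("A, B", "C, D", "E, F"))
  expect_equal(atomize("Silva, M. e Souza, R.")[[1]],
               c("Silva, M.", "Souza, R."))
  expect_equal(atomize("")[[1]], character(0))

  res <- atomize("Silva, M. et al.")
  expect_equal(res[[1]], "Silva, M.")
  expect_true(attr(res, "et_al"))
  res2 <- atomize(c("Silva, M.; et al.", "Mendes, V.C."))
  expect_equal(res2[[1]], "Silva, M.")
  expect_equal(attr(res2, "et_al"), c(TRUE, FALSE))

  expect_error(atomize("x", delimiters = character(0)), "nonempty")
})

test_that("normalization reaches the surname,initials token from both layouts", {
  expect_equal(unclass(normalize_collector("Proença, C.E.B."))[1],
               "proenca,ceb")
  expect_equal(unclass(normalize_collector("howard s. irwin"))[1], "irwin,hs")
  expect_equal(unclass(normalize_collector("Irwin, Howard Samuel"))[1],
               "irwin,hs")
  expect_equal(unclass(normalize_collector("J.A. Ratter"))[1], "ratter,ja")
  expect_equal(unclass(normalize_collector("RATTER, J. A."))[1], "ratter,ja")
  expect_equal(unclass(normalize_collector("Müller-Silva, É. T."))[1],
               "mullersilva,et")
})

test_that("normalization rejects non-name tokens with a reason", {
  res <- normalize_collector(c("123", "s.n.", "X", "Silva"))
  expect_true(all(is.na(res)))
  expect_equal(attr(res, "reason"),
               c("no alphabetic content", "stop-list token",
                 "fewer than 2 letters", "no initials"))
})

test_that("normalization is idempotent on its own tokens", {
  set.seed(3)
  raw <- c("Proença, C.E.B.", "howard s. irwin", "Faria, J.E.Q.",
           "Munhoz, C.B.R.", "A. E. R. Soares", "Câmara, P.E.A.S.")
  tok <- normalize_collector(raw)
  tok2 <- normalize_collector(tok)
  expect_equal(unclass(tok2)[seq_along(tok)], unclass(tok)[seq_along(tok)],
               ignore_attr = TRUE)
})

test_that("resolve fills de-duplicated ids in first-appearance order", {
  recs <- toy_records(list("x"), taxa = "T t")
  recs$recorded_by_raw <- "Ratter, J.A.; Irwin, H.S.; Ratter, J. A."
  attr(recs, "resolved") <- FALSE
  out <- resolve_collectors(recs)
  expect_equal(out$collector_ids[[1]], c("ratter,ja", "irwin,hs"))

  # same name twice collapses to one id (zero-diagonal precondition)
  recs$recorded_by_raw <- "A, B; A, B"
  expect_equal(resolve_collectors(recs)$collector_ids[[1]], "a,b")
})

test_that("resolve applies the name map and flags emptied records", {
  recs <- toy_records(list("x", "y"), taxa = c("T t", "U u"))
  recs$recorded_by_raw <- c("Irwin, H.", "et al.")
  attr(recs, "resolved") <- FALSE
  out <- resolve_collectors(recs, name_map = c("irwin,h" = "irwin,hs"))
  expect_equal(out$collector_ids[[1]], "irwin,hs")
  expect_equal(out$collector_ids[[2]], character(0))
  rep <- atomization_report(out)
  expect_equal(rep$et_al_flags, 1)
  expect_equal(rep$empty_after_resolution, out$record_id[2])
  expect_equal(rep$records_processed, 2)

  expect_error(
    resolve_collectors(recs, name_map = c("a,b" = "c,d", "a,b" = "e,f")),
    class = "collnet_config_error")
})

test_that("name maps load from two-column files with canonical self-mapping", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant\tcanonical", "irwin,h\tirwin,hs",
               "irwin,hsamuel\tirwin,hs"), f)
  map <- read_name_map(f)
  expect_equal(unname(map["irwin,h"]), "irwin,hs")
  expect_equal(unname(map["irwin,hs"]), "irwin,hs")
})

test_that("resolved id multiset matches the node sets of both models", {
  d <- generate_occurrences(generator_config(n_records = 300, seed = 9))
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(d$occurrences, f)
  recs <- resolve_collectors(read_occurrences(f),
                             name_map = d$truth$name_map)
  ids <- unique(unlist(recs$collector_ids))
  scn <- build_scn(filter_records(recs, record_filter_config(
    allowed_ranks = "species"))$kept)
  cwn <- build_cwn(extract_teams(recs))
  expect_setequal(rownames(scn$biadjacency), ids)
  expect_setequal(rownames(cwn$adjacency), ids)
})
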