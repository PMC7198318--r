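# a small hierarchy with references for view-collection tests
ref_fixture <- function() {
  h <- hierarchy(mk_nodes("g|group", "f|family|g", "f2|family|g",
                          "f3|family|g",
                          "o1|object|f", "o2|object|f", "od|object|f;f2"))
  h <- merge_contributors(h, data.frame(
    author_id = c("a", "a", "b", "c", "a"),
    node_id = c("f", "o1", "o1", "o2", "od")))
  refs <- data.frame(
    ref_id = sprintf("r%d", 1:7),
    title = paste("Title", 1:7),
    authors = c("Zed A;Young B", "Young B", "Archer C", "Baker D", "Cole E",
                "Dale F", "Early G"),
    venue = "J Test",
    year = c(2001L, 1999L, 2005L, 2001L, 2010L, 2011L, 2012L),
    external_id = c("doi:10.1/x", "", "", "", "", "", ""),
    stringsAsFactors = FALSE)
  links <- data.frame(
    node_id = c("f", "o1", "o2", "o1", "o2", "o2", "od", "f2"),
    ref_id  = c("r1", "r1", "r1", "r2", "r3", "r4", "r5", "r5"),
    stringsAsFactors = FALSE)
  merge_references(h, refs, links)
}

test_that("collecting a view unions and orders references and authors", {
  h <- ref_fixture()
  # family + 2 objects sharing one reference -> deduplicated to length 1
  v0 <- collect_view(h, "f", include_objects = FALSE)
  expect_equal(v0$references$ref_id, "r1")

  v <- collect_view(h, "f")
  # r1 linked from three members counted once; ordering by year then author
  expect_equal(v$references$ref_id, c("r2", "r4", "r1", "r3", "r5"))
  expect_equal(sum(v$references$ref_id == "r1"), 1L)
  # diamond object's reference r5 appears once from the grandparent view
  vg <- collect_view(h, "g")
  expect_equal(sum(vg$references$ref_id == "r5"), 1L)
  # merged authors ordered by contribution count, ties by name
  expect_equal(v$authors[1], "a")           # a contributed to 3 member nodes
  expect_equal(v$authors[-1], c("b", "c"))

  # disjoint reference lists union to their total
  h2 <- hierarchy(mk_nodes("g|group", "f|family|g", "x|object|f",
                           "y|object|f"))
  h2 <- merge_contributors(h2, data.frame(author_id = "a", node_id = "f"))
  refs2 <- data.frame(ref_id = sprintf("s%d", 1:6),
                      title = paste("T", 1:6), authors = "Au A",
                      venue = "V", year = 2000L, external_id = "",
                      stringsAsFactors = FALSE)
  links2 <- data.frame(node_id = rep(c("x", "y"), each = 3),
                       ref_id = sprintf("s%d", 1:6))
  h2 <- merge_references(h2, refs2, links2)
  expect_equal(nrow(collect_view(h2, "f")$references), 6L)

  expect_error(collect_view(h, "f3"), class = "citesum_empty_authors")
})

test_that("view reference unions never exceed the member sum", {
  db <- simulate_database(small_params(3, noise = 0.1))
  h <- db$hierarchy
  for (root in sample(h$nodes$node_id[h$nodes$level_kind == "family"], 5)) {
    members <- descendants(h, root)
    n_union <- length(unique(unlist(h$refs[members])))
    n_sum <- sum(lengths(h$refs[members]))
    expect_lte(n_union, n_sum)
  }
})

test_that("rendered summaries carry all eight elements deterministically", {
  h <- ref_fixture()
  v <- collect_view(h, "f")
  s <- render_summary(v, db_version = "2026.1", publisher = "Example Press")
  expect_true(all(summary_elements(s)))
  expect_match(s$title, "2026.1", fixed = TRUE)
  expect_error(render_summary(v, db_version = NULL, publisher = "P"),
               class = "citesum_bad_input")

  # re-rendering with the same inputs is byte-identical
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_summary(s, d1)
  f2 <- write_summary(render_summary(v, "2026.1", "Example Press"), d2)
  expect_identical(readLines(f1[1]), readLines(f2[1]))
  expect_identical(readLines(f1[2]), readLines(f2[2]))

  # the reference section numbers every entry: build a 166-reference view
  nref <- 166L
  h3 <- hierarchy(mk_nodes("g|group", "f|family|g"))
  h3 <- merge_contributors(h3, data.frame(author_id = "a", node_id = "f"))
  refs3 <- data.frame(ref_id = sprintf("q%03d", 1:nref),
                      title = paste("Q", 1:nref), authors = "Au A",
                      venue = "V", year = 2000L, external_id = "",
                      stringsAsFactors = FALSE)
  h3 <- merge_references(h3, refs3,
                         data.frame(node_id = "f",
                                    ref_id = sprintf("q%03d", 1:nref)))
  s3 <- render_summary(collect_view(h3, "f"), "1", "P")
  expect_equal(nrow(s3$references), nref)
  expect_true(any(grepl(paste0("^", nref, "\\. "), s3$markdown)))
})

test_that("citation exports are well-formed and round-trip", {
  h <- ref_fixture()
  s <- render_summary(collect_view(h, "f"), "2026.1", "Example Press")

  bib <- export_citation(s, "bibtex")
  parsed <- citesum:::parse_bibtex_entry(bib)
  expect_equal(attr(parsed, "entry_type"), "article")
  expect_equal(unname(parsed[["title"]]), s$title)
  expect_equal(unname(parsed[["doi"]]), s$doi)

  ris <- export_citation(s, "ris")
  expect_equal(ris[1], "TY  - JOUR")
  expect_equal(ris[length(ris)], "ER  - ")
  expect_equal(sum(startsWith(ris, "AU  - ")), length(s$authors))

  plain <- export_citation(s, "plain")
  expect_match(plain, "2026.1", fixed = TRUE)
  expect_error(export_citation(s, "endnote"))
})

test_that("metadata records validate and round-trip the ledger payload", {
  h <- ref_fixture()
  s <- render_summary(collect_view(h, "f"), "2026.1", "Example Press",
                      summary_version = "3")
  doc <- render_metadata(s)
  path <- withr::local_tempfile(fileext = ".xml")
  xml2::write_xml(doc, path)
  reread <- xml2::read_xml(path)  # well-formed
  meta <- parse_metadata(reread)
  expect_equal(meta$title, s$title)
  expect_equal(meta$creators, s$authors)
  entry <- meta$ledger
  expect_s3_class(entry, "ledger_entry")
  expect_equal(entry$view_id, "f")
  expect_equal(entry$db_version, "2026.1")
  expect_equal(entry$summary_version, "3")
  expect_setequal(entry$authors, s$authors)
  expect_setequal(entry$ref_ids, s$references$ref_id)
  expect_equal(entry$view_encoding, encode_view(s$view))
  # metadata -> parse -> metadata preserves the payload
  s2 <- s
  doc2 <- render_metadata(s2)
  expect_equal(parse_metadata(doc2)$ledger, entry)

  # one creator element per author
  many <- s
  many$authors <- sprintf("w%d", 1:7)
  many$affiliations <- rep("X", 7)
  doc7 <- render_metadata(many)
  expect_length(xml2::xml_find_all(doc7, ".//dc:creator"), 7L)
})
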