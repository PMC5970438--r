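classified_fixture <- function() {
  tab <- normalize_table(make_raw_table(
    header_rows = rows_of(c("Trait", "LOD", "Marker")),
    body_rows = rows_of(c("ascorbic acid", "3.5", "TG123"),
                        c("fruit shape", "4.1", "CT99"),
                        c("stem", "2.2", "TG123")),
    caption = "QTLs detected for fruit quality traits",
    table_id = "T1", article_id = "PMC1"))
  classify_columns(tab, test_index())
}

test_that("the table subject concatenates caption, expanded headings and footer", {
  tab <- normalize_table(make_raw_table(
    header_rows = rows_of(c("Trait", "LOD")),
    body_rows = rows_of(c("x", "1")),
    caption = "QTLs for fruit traits"))
  expect_equal(table_subject(tab), "QTLs for fruit traits Trait LOD")

  tab$caption <- ""
  expect_equal(table_subject(tab), "Trait LOD")
})

test_that("trait-table filtering is whole-word, plural-aware and monotone in keywords", {
  d <- is_trait_table("QTLs detected for fruit quality traits in tomato")
  expect_true(d$is_trait_table)
  expect_setequal(d$matched_keywords, c("trait", "qtl"))

  expect_false(
    is_trait_table("List of primers used in this study Primer Sequence")$
      is_trait_table)

  # a hit in a heading alone suffices (headings are part of the subject)
  tab <- normalize_table(make_raw_table(
    header_rows = rows_of(c("Trait", "Mean")),
    body_rows = rows_of(c("x", "1")),
    caption = "Summary of measurements"))
  expect_true(is_trait_table(table_subject(tab))$is_trait_table)

  # monotonicity: adding keywords never flips a positive decision
  set.seed(3)
  subjects <- c("QTL analysis of stem", "primer list", "phenotypes scored",
                "field seasons", "trait values per line")
  for (s in subjects) {
    base <- is_trait_table(s)$is_trait_table
    grown <- is_trait_table(s, c(default_keywords(), "stem", "line",
                                 "season"))$is_trait_table
    if (base) expect_true(grown)
  }
})

test_that("columns classify into descriptor, value and property", {
  tab <- classified_fixture()
  expect_equal(tab$headers$category, c("descriptor", "value", "property"))

  # keyword-free alphanumeric column with phenotypic cell matches is a
  # descriptor too
  tab2 <- classify_columns(normalize_table(make_raw_table(
    header_rows = rows_of(c("Character", "LOD")),
    body_rows = rows_of(c("fruit shape", "3.1"), c("stem", "2.0")))),
    test_index())
  expect_equal(tab2$headers$category[1], "descriptor")

  # unmatched alphanumeric columns stay unclassified
  tab3 <- classify_columns(normalize_table(make_raw_table(
    header_rows = rows_of(c("Line", "LOD")),
    body_rows = rows_of(c("IL-4-2", "3.1")))), test_index())
  expect_equal(tab3$headers$category, c("unclassified", "value"))
})

test_that("statements cover every non-descriptor column of rows with a subject", {
  tab <- classified_fixture()
  st <- extract_statements(tab)
  expect_length(st, 3)
  expect_equal(vapply(st, function(s) nrow(s$pairs), integer(1)),
               rep(2L, 3))

  s1 <- st[[1]]
  expect_equal(s1$subject_text, "ascorbic acid")
  expect_equal(s1$subject_term_id, "CHEBI:22652")
  expect_equal(s1$pairs$predicate, c("LOD", "Marker"))
  expect_equal(s1$pairs$object_text, c("3.5", "TG123"))
  expect_equal(s1$pairs$object_term_id, c(NA, "SGN-M123"))
  expect_equal(s1$pairs$column_category, c("value", "property"))

  # rows with an empty descriptor cell are skipped
  tab_gap <- classify_columns(normalize_table(make_raw_table(
    header_rows = rows_of(c("Trait", "LOD")),
    body_rows = rows_of(c("stem", "1.0"), c("", "2.0")))), test_index())
  expect_length(extract_statements(tab_gap), 1)

  # no descriptor column: no statements, with a message
  tab_none <- classify_columns(normalize_table(make_raw_table(
    header_rows = rows_of(c("Line", "LOD")),
    body_rows = rows_of(c("IL-1", "3.3")))), test_index())
  expect_message(out <- extract_statements(tab_none), "no descriptor")
  expect_length(out, 0)
})

test_that("statement counts equal rows with non-empty descriptors across a corpus", {
  corp <- generate_corpus(corpus_spec(n_articles = 4, seed = 13))
  docs <- lapply(corp$articles, function(a) read_article(a$xml))
  res <- suppressMessages(mine_corpus(docs,
                                      mini_dictionary(corp$marker_entries)))
  expected <- sum(vapply(res$trait_tables, function(t) {
    dc <- which(t$headers$category == "descriptor")[1]
    sum(nzchar(trimws(t$body[, dc])))
  }, numeric(1)))
  expect_equal(length(res$statements), expected)
})

test_that("merging groups the same trait across tables via concepts and expansions", {
  doc <- read_article(jats_article(
    pmcid = "PMC77",
    paragraphs = "Total ascorbic acid (AsA) content was measured.",
    tables = c(
      jats_table("T1", "QTLs for fruit traits",
                 header_rows = rows_of(c("Trait", "LOD")),
                 body_rows = rows_of(c("AsA", "3.3"))),
      jats_table("T3", "Trait QTLs in season two",
                 header_rows = rows_of(c("Trait", "LOD")),
                 body_rows = rows_of(c("ascorbic acid", "2.8"),
                                     c("stem", "1.9"))))))
  res <- suppressMessages(mine_corpus(list(doc), mini_dictionary()))
  groups <- merge_statements(res$statements)

  expect_true("CHEBI:22652" %in% names(groups))
  expect_length(groups[["CHEBI:22652"]], 2)
  expect_setequal(
    unique(vapply(groups[["CHEBI:22652"]], `[[`, character(1), "table_id")),
    c("T1", "T3"))

  # unannotated subjects differing only in case share a group
  mk <- function(subj) structure(
    list(article_id = "PMC1", table_id = "T1", row_index = 0L,
         subject_text = subj, subject_term_id = NA_character_,
         pairs = data.frame()), class = "qtl_statement")
  g <- merge_statements(list(mk("Plant Height"), mk("plant height"),
                             mk("width")))
  expect_length(g, 2)
  # the groups partition the input
  expect_equal(sum(lengths(g)), 3)
})
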