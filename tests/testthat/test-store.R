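mined_fixture <- function(n_articles = 2, seed = 9) {
  corp <- generate_corpus(corpus_spec(n_articles = n_articles, seed = seed))
  docs <- lapply(corp$articles, function(a) read_article(a$xml))
  suppressMessages(mine_corpus(docs, mini_dictionary(corp$marker_entries)))
}

empty_result <- function() {
  mining_result(
    articles = data.frame(article_id = character(0), title = character(0),
                          stringsAsFactors = FALSE),
    trait_tables = list(),
    abbreviations = data.frame(article_id = character(0),
                               short_form = character(0),
                               long_form = character(0),
                               source = character(0),
                               stringsAsFactors = FALSE),
    statements = list(),
    cell_concepts = data.frame(article_id = character(0),
                               table_id = character(0),
                               row = integer(0), col = integer(0),
                               term_id = character(0),
                               stringsAsFactors = FALSE),
    trait_decisions = data.frame(article_id = character(0),
                                 table_id = character(0),
                                 is_trait_table = logical(0),
                                 stringsAsFactors = FALSE))
}

sqlite_counts <- function(path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  tabs <- DBI::dbListTables(con)
  counts <- vapply(tabs, function(t) {
    DBI::dbGetQuery(con, paste0('SELECT COUNT(*) AS n FROM "', t, '"'))$n
  }, numeric(1))
  counts
}

test_that("the six-table schema is created and row counts are conserved", {
  db <- withr::local_tempfile(fileext = ".sqlite")
  write_sqlite(empty_result(), db)
  counts <- sqlite_counts(db)
  expect_setequal(names(counts),
                  c("ARTICLE", "TRAIT_TABLE", "ABBREVIATION", "QTL",
                    "COLUMN_ENTRY", "CELL_ENTRY"))
  expect_true(all(counts == 0))

  res <- mined_fixture()
  db2 <- withr::local_tempfile(fileext = ".sqlite")
  write_sqlite(res, db2)
  counts <- sqlite_counts(db2)
  expect_equal(unname(counts["QTL"]), length(res$statements))
  expect_equal(unname(counts["TRAIT_TABLE"]), length(res$trait_tables))
  expect_equal(unname(counts["ARTICLE"]), nrow(res$articles))
  expect_equal(unname(counts["ABBREVIATION"]), nrow(res$abbreviations))

  # refuse to clobber without the overwrite flag
  expect_error(write_sqlite(res, db2), "overwrite")
  expect_silent(write_sqlite(res, db2, overwrite = TRUE))
})

test_that("statements round-trip through the relational store", {
  res <- mined_fixture()
  db <- withr::local_tempfile(fileext = ".sqlite")
  write_sqlite(res, db)
  back <- read_statements_sqlite(db)
  expect_length(back, length(res$statements))
  key <- function(s) paste(s$article_id, s$table_id, s$row_index)
  ord <- function(ss) ss[order(vapply(ss, key, character(1)))]
  a <- ord(res$statements)
  b <- ord(back)
  for (i in seq_along(a)) {
    expect_equal(b[[i]]$subject_text, a[[i]]$subject_text)
    expect_equal(b[[i]]$subject_term_id, a[[i]]$subject_term_id)
    expect_equal(b[[i]]$pairs[order(b[[i]]$pairs$predicate), ],
                 a[[i]]$pairs[order(a[[i]]$pairs$predicate), ],
                 ignore_attr = TRUE)
  }
})

test_that("CSV output has one quoted row per predicate-object pair", {
  csv <- withr::local_tempfile(fileext = ".csv")
  write_statements_csv(list(), csv)
  expect_length(readLines(csv), 1)  # header only

  st <- structure(
    list(article_id = "PMC1", table_id = "T1", row_index = 0L,
         subject_text = "fruit, shape", subject_term_id = "SP:0000038",
         pairs = data.frame(
           predicate = c("LOD", "Marker"),
           object_text = c("3.5", "TG1, TG2"),
           object_term_id = c(NA, NA),
           column_category = c("value", "property"),
           stringsAsFactors = FALSE)),
    class = "qtl_statement")
  write_statements_csv(list(st), csv)
  lines <- readLines(csv)
  expect_length(lines, 3)
  parsed <- utils::read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(parsed$object_text[2], "TG1, TG2")  # comma survives quoting
  expect_equal(parsed$subject_text[1], "fruit, shape")
})

test_that("the triple count equals pairs plus annotated subjects", {
  res <- mined_fixture()
  nt <- withr::local_tempfile(fileext = ".nt")
  export_rdf(res$statements, nt, base_uri = "http://example.org/qtl")
  n_pairs <- sum(vapply(res$statements, function(s) nrow(s$pairs),
                        integer(1)))
  n_typed <- sum(vapply(res$statements, function(s) !is.na(s$subject_term_id),
                        logical(1)))
  lines <- readLines(nt)
  expect_equal(length(lines), n_pairs + n_typed)
  expect_true(all(grepl(" \\.$", lines)))

  # annotated subjects and objects become identifiers.org URIs
  annotated <- structure(
    list(article_id = "PMC1", table_id = "T1", row_index = 0L,
         subject_text = "fruit shape", subject_term_id = "SP:0000038",
         pairs = data.frame(predicate = "Compound", object_text = "ascorbic acid",
                            object_term_id = "CHEBI:22652",
                            column_category = "property",
                            stringsAsFactors = FALSE)),
    class = "qtl_statement")
  export_rdf(list(annotated), nt)
  alines <- readLines(nt)
  expect_length(alines, 2)  # one typing triple + one pair triple
  expect_true(any(grepl("<http://identifiers.org/CHEBI:22652> \\.$", alines)))
  expect_true(any(grepl("identifiers.org/SP:0000038", alines, fixed = TRUE)))

  # unannotated objects are plain literals
  one <- structure(
    list(article_id = "PMC1", table_id = "T1", row_index = 0L,
         subject_text = "plain", subject_term_id = NA_character_,
         pairs = data.frame(predicate = "LOD", object_text = "3.5",
                            object_term_id = NA_character_,
                            column_category = "value",
                            stringsAsFactors = FALSE)),
    class = "qtl_statement")
  export_rdf(list(one), nt)
  lines <- readLines(nt)
  expect_length(lines, 1)
  expect_match(lines, '"3\\.5"')

  expect_error(export_rdf(list(), nt, base_uri = "not a uri"), "absolute")
})
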