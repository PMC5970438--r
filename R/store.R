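# Persistence: relational (SQLite) store, CSV and RDF N-Triples export.

#' Assemble a mining result
#'
#' Bundles the per-corpus artifacts into a single `mining_result`
#' container consumed by the writers and the evaluation harness.
#'
#' @param articles Data frame with columns `article_id`, `title`.
#' @param trait_tables List of classified `normalized_table`s that passed
#'   the trait-table filter.
#' @param abbreviations Data frame with `article_id`, `short_form`,
#'   `long_form`, `source`.
#' @param statements List of `qtl_statement`s.
#' @param cell_concepts Data frame of concept matches with `article_id`,
#'   `table_id`, `row`, `col`, `term_id`, `label`, `category`, `source`,
#'   `matched_text`.
#' @param trait_decisions Data frame with `article_id`, `table_id`,
#'   `is_trait_table`.
#' @return An object of class `mining_result`.
#' @export
mining_result <- function(articles, trait_tables, abbreviations,
                          statements, cell_concepts, trait_decisions) {
  structure(
    list(articles = articles, trait_tables = trait_tables,
         abbreviations = abbreviations, statements = statements,
         cell_concepts = cell_concepts, trait_decisions = trait_decisions),
    class = "mining_result")
}

#' @export
print.mining_result <- function(x, ...) {
  cat("<mining_result>\n")
  cat("  articles:      ", nrow(x$articles), "\n", sep = "")
  cat("  trait tables:  ", length(x$trait_tables), "\n", sep = "")
  cat("  abbreviations: ", nrow(x$abbreviations), "\n", sep = "")
  cat("  statements:    ", length(x$statements), "\n", sep = "")
  cat("  cell concepts: ", nrow(x$cell_concepts), "\n", sep = "")
  invisible(x)
}

table_key <- function(article_id, table_id) {
  paste(article_id, table_id, sep = ":")
}

#' Write a mining result to an SQLite database
#'
#' Creates the six-table relational schema — `ARTICLE`, `TRAIT_TABLE`,
#' `ABBREVIATION`, `QTL`, `COLUMN_ENTRY` and `CELL_ENTRY` — with foreign
#' keys from `TRAIT_TABLE` to `ARTICLE` and from `COLUMN_ENTRY`,
#' `CELL_ENTRY` and `QTL` to `TRAIT_TABLE`; `ABBREVIATION` is keyed to
#' `ARTICLE`. One `QTL` row is written per statement; predicate-object
#' pairs are reconstructable by joining `QTL` with `CELL_ENTRY` and
#' `COLUMN_ENTRY` (see [read_statements_sqlite()]).
#'
#' @param result A `mining_result`.
#' @param path Database file path.
#' @param overwrite Overwrite an existing file? Default `FALSE` (refuse).
#' @return `path`, invisibly.
#' @export
write_sqlite <- function(result, path, overwrite = FALSE) {
  stopifnot(inherits(result, "mining_result"))
  if (file.exists(path)) {
    if (!overwrite) stop("file exists: ", path,
                         " (use overwrite = TRUE)", call. = FALSE)
    unlink(path)
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  DBI::dbExecute(con, "
    CREATE TABLE ARTICLE (
      article_id TEXT PRIMARY KEY,
      title TEXT)")
  DBI::dbExecute(con, "
    CREATE TABLE TRAIT_TABLE (
      table_key TEXT PRIMARY KEY,
      article_id TEXT NOT NULL REFERENCES ARTICLE(article_id),
      table_id TEXT, label TEXT, caption TEXT, footer TEXT,
      orientation TEXT, n_rows INTEGER, n_cols INTEGER)")
  DBI::dbExecute(con, "
    CREATE TABLE ABBREVIATION (
      article_id TEXT NOT NULL REFERENCES ARTICLE(article_id),
      short_form TEXT, long_form TEXT, source TEXT)")
  DBI::dbExecute(con, "
    CREATE TABLE COLUMN_ENTRY (
      table_key TEXT NOT NULL REFERENCES TRAIT_TABLE(table_key),
      col_index INTEGER, raw_heading TEXT, expanded_heading TEXT,
      datatype TEXT, category TEXT)")
  DBI::dbExecute(con, "
    CREATE TABLE CELL_ENTRY (
      table_key TEXT NOT NULL REFERENCES TRAIT_TABLE(table_key),
      row_index INTEGER, col_index INTEGER,
      raw_text TEXT, expanded_text TEXT, term_id TEXT)")
  DBI::dbExecute(con, "
    CREATE TABLE QTL (
      qtl_id INTEGER PRIMARY KEY,
      table_key TEXT NOT NULL REFERENCES TRAIT_TABLE(table_key),
      article_id TEXT NOT NULL REFERENCES ARTICLE(article_id),
      row_index INTEGER, subject_text TEXT, subject_term_id TEXT,
      n_pairs INTEGER)")

  if (nrow(result$articles) > 0) {
    DBI::dbWriteTable(con, "ARTICLE",
                      result$articles[c("article_id", "title")],
                      append = TRUE)
  }
  for (tab in result$trait_tables) {
    tk <- table_key(tab$source$article_id, tab$source$table_id)
    DBI::dbWriteTable(con, "TRAIT_TABLE", data.frame(
      table_key = tk, article_id = tab$source$article_id,
      table_id = tab$source$table_id, label = tab$source$label,
      caption = tab$caption, footer = tab$footer,
      orientation = tab$orientation,
      n_rows = nrow(tab$body), n_cols = ncol(tab$body),
      stringsAsFactors = FALSE), append = TRUE)
    if (nrow(tab$headers) > 0) {
      DBI::dbWriteTable(con, "COLUMN_ENTRY", data.frame(
        table_key = tk, col_index = tab$headers$index,
        raw_heading = tab$headers$raw_heading,
        expanded_heading = tab$headers$expanded_heading,
        datatype = tab$headers$datatype,
        category = tab$headers$category,
        stringsAsFactors = FALSE), append = TRUE)
    }
    if (length(tab$body) > 0) {
      cc <- result$cell_concepts
      cc <- cc[cc$article_id == tab$source$article_id &
                 cc$table_id == tab$source$table_id, , drop = FALSE]
      idx <- expand.grid(row = seq_len(nrow(tab$body)) - 1L,
                         col = seq_len(ncol(tab$body)) - 1L)
      term <- rep(NA_character_, nrow(idx))
      if (nrow(cc) > 0) {
        key <- paste(idx$row, idx$col)
        ckey <- paste(cc$row, cc$col)
        term <- cc$term_id[match(key, ckey)]
      }
      DBI::dbWriteTable(con, "CELL_ENTRY", data.frame(
        table_key = tk, row_index = idx$row, col_index = idx$col,
        raw_text = as.vector(tab$body_raw),
        expanded_text = as.vector(tab$body),
        term_id = term, stringsAsFactors = FALSE), append = TRUE)
    }
  }
  if (nrow(result$abbreviations) > 0) {
    DBI::dbWriteTable(con, "ABBREVIATION", result$abbreviations[
      c("article_id", "short_form", "long_form", "source")], append = TRUE)
  }
  for (s in result$statements) {
    DBI::dbWriteTable(con, "QTL", data.frame(
      table_key = table_key(s$article_id, s$table_id),
      article_id = s$article_id, row_index = s$row_index,
      subject_text = s$subject_text, subject_term_id = s$subject_term_id,
      n_pairs = nrow(s$pairs), stringsAsFactors = FALSE), append = TRUE)
  }
  invisible(path)
}

#' Read QTL statements back from an SQLite store
#'
#' Reconstructs each statement's predicate-object pairs by joining the
#' `QTL` rows with `CELL_ENTRY` and `COLUMN_ENTRY`.
#'
#' @param path Database file written by [write_sqlite()].
#' @return List of `qtl_statement`s.
#' @export
read_statements_sqlite <- function(path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  qtl <- DBI::dbReadTable(con, "QTL")
  cols <- DBI::dbReadTable(con, "COLUMN_ENTRY")
  cells <- DBI::dbReadTable(con, "CELL_ENTRY")
  tabs <- DBI::dbReadTable(con, "TRAIT_TABLE")
  statements <- list()
  for (i in seq_len(nrow(qtl))) {
    tk <- qtl$table_key[i]
    tcols <- cols[cols$table_key == tk, , drop = FALSE]
    tcols <- tcols[order(tcols$col_index), , drop = FALSE]
    desc_col <- tcols$col_index[tcols$category == "descriptor"][1]
    row_cells <- cells[cells$table_key == tk &
                         cells$row_index == qtl$row_index[i], , drop = FALSE]
    row_cells <- row_cells[order(row_cells$col_index), , drop = FALSE]
    keep <- row_cells$col_index != desc_col & nzchar(row_cells$expanded_text)
    rc <- row_cells[keep, , drop = FALSE]
    m <- match(rc$col_index, tcols$col_index)
    pairs <- data.frame(
      predicate = tcols$expanded_heading[m],
      object_text = rc$expanded_text,
      object_term_id = rc$term_id,
      column_category = ifelse(tcols$category[m] == "value",
                               "value", "property"),
      stringsAsFactors = FALSE)
    statements[[length(statements) + 1L]] <- structure(
      list(article_id = qtl$article_id[i],
           table_id = tabs$table_id[match(tk, tabs$table_key)],
           row_index = qtl$row_index[i],
           subject_text = qtl$subject_text[i],
           subject_term_id = qtl$subject_term_id[i],
           pairs = pairs),
      class = "qtl_statement")
  }
  statements
}

#' Flatten statements to a data frame (one row per predicate-object pair)
#'
#' @param statements List of `qtl_statement`s.
#' @return Data frame with columns `article_id`, `table_id`, `row_index`,
#'   `subject_text`, `subject_term_id`, `predicate`, `object_text`,
#'   `object_term_id`, `column_category`.
#' @export
statements_to_df <- function(statements) {
  empty <- data.frame(
    article_id = character(0), table_id = character(0),
    row_index = integer(0), subject_text = character(0),
    subject_term_id = character(0), predicate = character(0),
    object_text = character(0), object_term_id = character(0),
    column_category = character(0), stringsAsFactors = FALSE)
  if (length(statements) == 0) return(empty)
  rows <- lapply(statements, function(s) {
    if (nrow(s$pairs) == 0) return(NULL)
    data.frame(
      article_id = s$article_id, table_id = s$table_id,
      row_index = s$row_index, subject_text = s$subject_text,
      subject_term_id = s$subject_term_id,
      s$pairs, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write QTL statements to CSV
#'
#' One data row per (statement, predicate-object pair), RFC 4180 quoting,
#' preceded by a header row.
#'
#' @param statements List of `qtl_statement`s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_statements_csv <- function(statements, path) {
  df <- statements_to_df(statements)
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

slugify <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

identifiers_uri <- function(curie) {
  paste0("http://identifiers.org/", curie)
}

#' Export QTL statements as RDF N-Triples
#'
#' Mints one resource per statement row
#' (`<base>/article/<pmcid>/table/<table>/row/<row>`), writes one triple
#' per predicate-object pair (predicate URI
#' `<base>/property/<slug(heading)>`, object an identifiers.org URI when
#' annotated, otherwise a plain literal), plus one `rdf:type` triple
#' linking the subject to its trait concept when the subject was
#' annotated. Total triple count is therefore the number of pairs plus
#' the number of statements with an annotated subject.
#'
#' @param statements List of `qtl_statement`s.
#' @param path Output file path (N-Triples).
#' @param base_uri Absolute URI prefix used to mint resources.
#' @return `path`, invisibly.
#' @export
export_rdf <- function(statements, path,
                       base_uri = "http://example.org/qtlminer") {
  if (!grepl("^[a-zA-Z][a-zA-Z0-9+.-]*://", base_uri)) {
    stop("base_uri must be an absolute URI prefix", call. = FALSE)
  }
  base_uri <- sub("/+$", "", base_uri)
  rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  lines <- character(0)
  for (s in statements) {
    subj <- sprintf("<%s/article/%s/table/%s/row/%d>",
                    base_uri, s$article_id, s$table_id, s$row_index)
    if (!is.na(s$subject_term_id)) {
      lines <- c(lines, sprintf("%s <%s> <%s> .", subj, rdf_type,
                                identifiers_uri(s$subject_term_id)))
    }
    for (k in seq_len(nrow(s$pairs))) {
      pred <- sprintf("<%s/property/%s>", base_uri,
                      slugify(s$pairs$predicate[k]))
      obj <- if (!is.na(s$pairs$object_term_id[k])) {
        sprintf("<%s>", identifiers_uri(s$pairs$object_term_id[k]))
      } else {
        sprintf('"%s"', escape_literal(s$pairs$object_text[k]))
      }
      lines <- c(lines, sprintf("%s %s %s .", subj, pred, obj))
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
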