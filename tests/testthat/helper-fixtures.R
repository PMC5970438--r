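# Builders and oracles shared across the test files. All fixtures are
# constructed in code; nothing is read from disk except the bundled
# mini-dictionary.

cellspec <- function(text, rowspan = 1, colspan = 1) {
  list(text = text, rowspan = as.integer(rowspan),
       colspan = as.integer(colspan))
}

# rows given as character vectors become rows of span-1 cells
rows_of <- function(...) {
  lapply(list(...), function(r) {
    if (is.character(r)) lapply(r, cellspec) else r
  })
}

make_raw_table <- function(body_rows, header_rows = list(), caption = "",
                           footer = "", table_id = "tbl1",
                           label = "Table 1", article_id = "PMC1") {
  structure(
    list(table_id = table_id, label = label, caption = caption,
         footer = footer, header_cells = header_rows,
         body_cells = body_rows, article_id = article_id),
    class = "raw_table")
}

xml_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Minimal JATS table-wrap; header/body rows are character vectors or
# lists of cellspec()s.
jats_table <- function(id, caption, body_rows, header_rows = list(),
                       footer = "", label = NULL) {
  row_xml <- function(cells, tag) {
    cells <- lapply(cells, function(c) if (is.character(c)) cellspec(c) else c)
    paste0("<tr>", paste(vapply(cells, function(c) {
      attrs <- ""
      if (c$rowspan > 1) attrs <- paste0(attrs, ' rowspan="', c$rowspan, '"')
      if (c$colspan > 1) attrs <- paste0(attrs, ' colspan="', c$colspan, '"')
      paste0("<", tag, attrs, ">", xml_esc(c$text), "</", tag, ">")
    }, character(1)), collapse = ""), "</tr>")
  }
  thead <- if (length(header_rows) > 0) {
    paste0("<thead>",
           paste(vapply(header_rows, row_xml, character(1), tag = "th"),
                 collapse = ""), "</thead>")
  } else ""
  foot <- if (nzchar(footer)) {
    paste0("<table-wrap-foot><p>", xml_esc(footer), "</p></table-wrap-foot>")
  } else ""
  paste0('<table-wrap id="', id, '">',
         if (!is.null(label)) paste0("<label>", label, "</label>"),
         "<caption><p>", xml_esc(caption), "</p></caption><table>", thead,
         "<tbody>",
         paste(vapply(body_rows, row_xml, character(1), tag = "td"),
               collapse = ""),
         "</tbody></table>", foot, "</table-wrap>")
}

jats_article <- function(pmcid = "PMC1234", paragraphs = character(),
                         tables = character(), title = "A mapping study") {
  paste0('<?xml version="1.0" encoding="UTF-8"?>',
         "<article><front><article-meta>",
         '<article-id pub-id-type="pmcid">', pmcid, "</article-id>",
         "<title-group><article-title>", xml_esc(title),
         "</article-title></title-group></article-meta></front><body>",
         paste(vapply(paragraphs, function(p) {
           paste0("<p>", xml_esc(p), "</p>")
         }, character(1)), collapse = ""),
         paste(tables, collapse = ""),
         "</body></article>")
}

# Brute-force long-form oracle: enumerate every word-start position whose
# character equals the short form's first character and check that the
# remaining alphanumeric characters occur in order to its right; the
# rightmost valid start gives the shortest suffix. Post-conditions mirror
# best_long_form's validity checks.
oracle_long_form <- function(short_form, window) {
  lch <- strsplit(tolower(window), "")[[1]]
  sch <- strsplit(tolower(short_form), "")[[1]]
  sch <- sch[grepl("[\\p{L}\\p{N}]", sch, perl = TRUE)]
  if (length(sch) == 0 || length(lch) == 0) return(NULL)
  is_alnum <- function(ch) grepl("[\\p{L}\\p{N}]", ch, perl = TRUE)
  subseq_after <- function(p) {
    rest <- sch[-1]
    i <- p + 1L
    for (ch in rest) {
      while (i <= length(lch) && lch[i] != ch) i <- i + 1L
      if (i > length(lch)) return(FALSE)
      i <- i + 1L
    }
    TRUE
  }
  starts <- Filter(function(p) {
    lch[p] == sch[1] && (p == 1 || !is_alnum(lch[p - 1])) && subseq_after(p)
  }, seq_along(lch))
  if (length(starts) == 0) return(NULL)
  lf <- trimws(substring(window, max(unlist(starts))))
  if (!nzchar(lf)) return(NULL)
  if (nchar(lf) < nchar(short_form)) return(NULL)
  if (identical(tolower(lf), tolower(short_form))) return(NULL)
  lf
}

# Random fully-tiled span layout (cells with rowspan/colspan up to 3);
# placement follows the first-free-column rule, so resolve_spans can
# reproduce it without overlap.
random_span_rows <- function(n_rows, n_cols) {
  occ <- matrix(FALSE, n_rows, n_cols)
  rows <- vector("list", n_rows)
  for (i in seq_len(n_rows)) {
    cells <- list()
    j <- 1L
    while (j <= n_cols) {
      if (occ[i, j]) {
        j <- j + 1L
        next
      }
      max_cs <- 0L
      while (j + max_cs <= n_cols && !occ[i, j + max_cs]) {
        max_cs <- max_cs + 1L
      }
      cs <- sample.int(min(max_cs, 3L), 1)
      rs <- sample.int(min(n_rows - i + 1L, 3L), 1)
      occ[i:(i + rs - 1L), j:(j + cs - 1L)] <- TRUE
      cells[[length(cells) + 1L]] <- cellspec(
        sprintf("c%d_%d", i, j), rs, cs)
      j <- j + cs
    }
    rows[[i]] <- cells
  }
  rows
}

# Dictionary index over the bundled mini-dictionary plus a couple of
# synthetic markers, reused across semantics tests.
test_index <- function() {
  markers <- list(
    list(term_id = "SGN-M123", label = "TG123", synonyms = character(0),
         source = "SGN-markers", category = "marker"),
    list(term_id = "SGN-M99", label = "CT99", synonyms = character(0),
         source = "SGN-markers", category = "marker"))
  build_index(mini_dictionary(markers))
}
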