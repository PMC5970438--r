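#' Fetch a full-text article from Europe PMC as JATS XML
#'
#' Retrieves the full text of an open-access article by its PMC identifier
#' from the Europe PMC RESTful API (`fullTextXML` endpoint) and caches the
#' raw XML on disk so that subsequent calls are reproducible offline.
#'
#' @param pmcid PMC identifier, e.g. `"PMC4266912"`.
#' @param cache_dir Directory where fetched XML is cached, one file per
#'   article named `<PMCID>.xml`.
#' @param offline If `TRUE`, never touch the network; a cached file must
#'   already exist in `cache_dir`.
#' @return An `article_doc` object (see [read_article()]).
#' @seealso [read_article()], [extract_tables()]
#' @export
fetch_fulltext <- function(pmcid, cache_dir = tempdir(), offline = FALSE) {
  if (!grepl("^PMC[0-9]+$", pmcid)) {
    stop("invalid PMC identifier: ", pmcid, call. = FALSE)
  }
  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  cache_file <- file.path(cache_dir, paste0(pmcid, ".xml"))
  if (!file.exists(cache_file)) {
    if (offline) {
      stop("no cached full text for ", pmcid, " in ", cache_dir,
           " (offline mode)", call. = FALSE)
    }
    url <- sprintf(
      "https://www.ebi.ac.uk/europepmc/webservices/rest/%s/fullTextXML",
      pmcid)
    ok <- tryCatch(
      utils::download.file(url, cache_file, quiet = TRUE, mode = "wb"),
      error = function(e) -1L, warning = function(w) -1L)
    if (!identical(ok, 0L) || !file.size(cache_file) > 0) {
      unlink(cache_file)
      stop("could not retrieve full text for ", pmcid,
           " (not open access, or network failure)", call. = FALSE)
    }
  }
  read_article(cache_file, pmcid = pmcid)
}

#' Read a JATS XML article from a file or string
#'
#' Parses a JATS-compliant XML document into an `article_doc`: the PMC
#' identifier, title, raw XML text and the plain-text body paragraphs
#' (used later to search for abbreviation definitions). Table-wrap content
#' is excluded from the body paragraphs; tables are parsed separately by
#' [extract_tables()].
#'
#' @param x Path to an XML file, or a single string of XML text.
#' @param pmcid Optional PMC identifier; if missing it is taken from the
#'   `article-id[@pub-id-type="pmcid"]` element, else from the file name.
#' @return An object of class `article_doc` with fields `pmcid`, `title`,
#'   `xml_text` and `body_paragraphs`.
#' @export
read_article <- function(x, pmcid = NULL) {
  if (length(x) != 1 || !is.character(x)) {
    stop("`x` must be a file path or an XML string", call. = FALSE)
  }
  is_path <- !grepl("^[[:space:]]*<", x)
  xml_text <- if (is_path) {
    paste(readLines(x, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  } else {
    x
  }
  doc <- xml2::read_xml(xml_text)  # parse error propagates to the caller

  if (is.null(pmcid)) {
    id_node <- xml2::xml_find_first(
      doc, ".//*[local-name()='article-id'][@pub-id-type='pmcid']")
    if (!inherits(id_node, "xml_missing")) {
      pmcid <- squish(xml2::xml_text(id_node))
      if (!grepl("^PMC", pmcid)) pmcid <- paste0("PMC", pmcid)
    } else if (is_path) {
      pmcid <- sub("\\.xml$", "", basename(x))
    } else {
      pmcid <- "PMC0000000"
    }
  }

  title_node <- xml2::xml_find_first(doc, ".//*[local-name()='article-title']")
  title <- if (inherits(title_node, "xml_missing")) "" else
    squish(xml2::xml_text(title_node))

  paras <- xml2::xml_find_all(
    doc,
    paste0(".//*[local-name()='body']//*[local-name()='p']",
           "[not(ancestor::*[local-name()='table-wrap'])]"))
  body_paragraphs <- vapply(paras, function(p) squish(xml2::xml_text(p)),
                            character(1))
  body_paragraphs <- body_paragraphs[nzchar(body_paragraphs)]

  structure(
    list(pmcid = pmcid, title = title, xml_text = xml_text,
         body_paragraphs = body_paragraphs),
    class = "article_doc")
}

#' @export
print.article_doc <- function(x, ...) {
  cat("<article_doc> ", x$pmcid, "\n", sep = "")
  if (nzchar(x$title)) cat("  title: ", x$title, "\n", sep = "")
  cat("  body paragraphs: ", length(x$body_paragraphs), "\n", sep = "")
  invisible(x)
}

new_raw_cell <- function(text, rowspan = 1L, colspan = 1L) {
  list(text = text, rowspan = as.integer(rowspan), colspan = as.integer(colspan))
}

# One <tr>'s cells (td/th) as a list of raw cells with span attributes.
parse_row_cells <- function(tr) {
  cells <- xml2::xml_find_all(
    tr, "./*[local-name()='td' or local-name()='th']")
  lapply(cells, function(cell) {
    rs <- suppressWarnings(as.integer(xml2::xml_attr(cell, "rowspan")))
    cs <- suppressWarnings(as.integer(xml2::xml_attr(cell, "colspan")))
    if (is.na(rs) || rs < 1) rs <- 1L
    if (is.na(cs) || cs < 1) cs <- 1L
    # xml_text flattens inline markup (italic, sup, ...) to plain characters
    new_raw_cell(squish(xml2::xml_text(cell)), rs, cs)
  })
}

#' Extract raw tables from a JATS article
#'
#' Finds every `<table-wrap>` element in the article body (matched by local
#' name, so JATS namespace dialects are accepted) and returns one
#' `raw_table` per element, in document order. Caption and footer text are
#' taken from the table-wrap's caption and foot elements; header and body
#' cells keep their `rowspan`/`colspan` attributes (default 1). Inline
#' markup is flattened to its text content, so footnote glyphs such as
#' `**` or superscript letters survive into the cell text.
#'
#' @param doc An `article_doc` from [read_article()] or [fetch_fulltext()].
#' @return A list of `raw_table` objects, each with fields `table_id`,
#'   `label`, `caption`, `footer`, `header_cells` and `body_cells` (lists
#'   of rows of cells, each cell a list with `text`, `rowspan`, `colspan`).
#' @export
extract_tables <- function(doc) {
  stopifnot(inherits(doc, "article_doc"))
  xml <- xml2::read_xml(doc$xml_text)
  wraps <- xml2::xml_find_all(xml, ".//*[local-name()='table-wrap']")
  out <- list()
  for (i in seq_along(wraps)) {
    wrap <- wraps[[i]]
    grid <- xml2::xml_find_first(wrap, ".//*[local-name()='table']")
    if (inherits(grid, "xml_missing")) {
      warning("table-wrap without a table grid skipped in ", doc$pmcid,
              call. = FALSE)
      next
    }
    table_id <- xml2::xml_attr(wrap, "id")
    if (is.na(table_id) || !nzchar(table_id)) table_id <- paste0("tbl", i)

    label_node <- xml2::xml_find_first(wrap, "./*[local-name()='label']")
    label <- if (inherits(label_node, "xml_missing")) "" else
      squish(xml2::xml_text(label_node))
    cap_node <- xml2::xml_find_first(wrap, "./*[local-name()='caption']")
    caption <- if (inherits(cap_node, "xml_missing")) "" else
      squish(xml2::xml_text(cap_node))
    foot_node <- xml2::xml_find_first(wrap,
                                      "./*[local-name()='table-wrap-foot']")
    footer <- if (inherits(foot_node, "xml_missing")) "" else
      squish(xml2::xml_text(foot_node))

    head_rows <- xml2::xml_find_all(
      grid, ".//*[local-name()='thead']//*[local-name()='tr']")
    body_rows <- xml2::xml_find_all(
      grid,
      paste0(".//*[local-name()='tr']",
             "[not(ancestor::*[local-name()='thead'])]"))

    out[[length(out) + 1L]] <- structure(
      list(table_id = table_id, label = label, caption = caption,
           footer = footer,
           header_cells = lapply(head_rows, parse_row_cells),
           body_cells = lapply(body_rows, parse_row_cells),
           article_id = doc$pmcid),
      class = "raw_table")
  }
  out
}

#' @export
print.raw_table <- function(x, ...) {
  cat("<raw_table> ", x$article_id, " / ", x$table_id,
      if (nzchar(x$label)) paste0(" (", x$label, ")"), "\n", sep = "")
  cat("  header rows: ", length(x$header_cells),
      ", body rows: ", length(x$body_cells), "\n", sep = "")
  invisible(x)
}
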