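# Table normalization: span resolution, orientation, header merging,
# datatype inference. Grids are plain character matrices; every cell is
# addressable by (row, column) indices.

resolve_grid <- function(rows) {
  if (length(rows) == 0) {
    m <- matrix(character(0), nrow = 0, ncol = 0)
    attr(m, "covered") <- 0L
    return(m)
  }
  nr <- length(rows)
  nc <- max(1L, sum(vapply(rows[[1]], function(c) c$colspan, integer(1))))
  m <- matrix(NA_character_, nrow = nr, ncol = nc)

  grow <- function(m, nr2, nc2) {
    if (nr2 > nrow(m)) {
      m <- rbind(m, matrix(NA_character_, nr2 - nrow(m), ncol(m)))
    }
    if (nc2 > ncol(m)) {
      m <- cbind(m, matrix(NA_character_, nrow(m), nc2 - ncol(m)))
    }
    m
  }

  covered <- 0L
  for (i in seq_along(rows)) {
    j <- 1L
    for (cell in rows[[i]]) {
      if (i > nrow(m)) m <- grow(m, i, ncol(m))
      while (j <= ncol(m) && !is.na(m[i, j])) j <- j + 1L
      rs <- cell$rowspan
      cs <- cell$colspan
      m <- grow(m, i + rs - 1L, j + cs - 1L)
      block <- m[i:(i + rs - 1L), j:(j + cs - 1L)]
      if (any(!is.na(block))) {
        stop("overlapping spans at row ", i, ", column ", j, call. = FALSE)
      }
      m[i:(i + rs - 1L), j:(j + cs - 1L)] <- cell$text
      covered <- covered + rs * cs
      j <- j + cs
    }
  }
  m[is.na(m)] <- ""
  attr(m, "covered") <- covered
  m
}

#' Resolve row/column spans into rectangular grids
#'
#' Replicates each cell with `rowspan` r and `colspan` c into all r x c
#' covered grid positions, following the usual HTML/JATS placement rule
#' (each cell occupies the first free column of its row). Ragged rows are
#' padded with empty strings so both result grids are rectangular. Two
#' cells claiming one position is a normalization error.
#'
#' @param header_cells,body_cells Lists of rows of raw cells (as produced
#'   by [extract_tables()]); each cell is a list with `text`, `rowspan`,
#'   `colspan`.
#' @return A list with character matrices `header` and `body` and the
#'   total number of `covered` grid positions (equal to the sum of
#'   `rowspan * colspan` over all input cells).
#' @export
resolve_spans <- function(header_cells, body_cells) {
  h <- resolve_grid(header_cells)
  b <- resolve_grid(body_cells)
  covered <- attr(h, "covered") + attr(b, "covered")
  attr(h, "covered") <- NULL
  attr(b, "covered") <- NULL
  list(header = h, body = b, covered = covered)
}

num_pattern <- "^[+-]?([0-9]+|[0-9]*\\.[0-9]+|[0-9]+\\.[0-9]*)([eE][+-]?[0-9]+)?$"
thousands_pattern <- "^[+-]?[0-9]{1,3}(,[0-9]{3})+(\\.[0-9]+)?$"
# Footnote glyphs: daggers/asterisks plus superscript letters; JATS <sup>
# markers flatten to plain letters, so a trailing plain-letter run after a
# digit is stripped too.
glyph_pattern <- paste0(
  "([*†‡§",
  "ᵃᵇᶜᵈᵉᶠᵍʰⁱʲᵏ",
  "ˡᵐⁿᵒᵖʳˢᵗᵘᵛʷ",
  "ˣʸᶻ]+|(?<=[0-9])[a-z]{1,2})$")

strip_footnote_glyphs <- function(x) {
  gsub(glyph_pattern, "", x, perl = TRUE)
}

is_numeric_cell <- function(x, strip = FALSE) {
  x <- trimws(x)
  if (strip) x <- strip_footnote_glyphs(x)
  nzchar(x) & (grepl(num_pattern, x) | grepl(thousands_pattern, x))
}

#' Infer the datatype of a table column
#'
#' A cell is numeric-parsable when, after optional stripping of trailing
#' footnote glyphs (`*`, daggers, section marks, superscript letters) and
#' of thousands separators, it parses as an integer, decimal, signed or
#' scientific-notation number. The column is `"numeric"` iff all
#' non-empty cells are numeric-parsable and at least one cell is
#' non-empty; otherwise `"alphanumeric"`. Decimal commas are not accepted.
#'
#' The default (`strip_glyphs = FALSE`) reproduces the legacy behaviour in
#' which a numeric column carrying `**` marks is read as alphanumeric — a
#' documented source of spurious downstream statements; stripping is
#' recommended for production runs.
#'
#' @param cells Character vector of cell texts (one column).
#' @param strip_glyphs Strip trailing footnote glyphs before parsing?
#' @return `"numeric"` or `"alphanumeric"`.
#' @export
infer_datatype <- function(cells, strip_glyphs = FALSE) {
  cells <- trimws(cells)
  nonempty <- nzchar(cells)
  if (!any(nonempty)) return("alphanumeric")
  if (all(is_numeric_cell(cells[nonempty], strip = strip_glyphs))) {
    "numeric"
  } else {
    "alphanumeric"
  }
}

# Mean within-line datatype purity for rows or columns of a character
# matrix; empty cells are ignored, all-empty lines are dropped.
homogeneity <- function(m, margin, strip_glyphs = FALSE) {
  scores <- apply(m, margin, function(v) {
    v <- trimws(v)
    v <- v[nzchar(v)]
    if (length(v) == 0) return(NA_real_)
    k <- sum(is_numeric_cell(v, strip = strip_glyphs))
    max(k, length(v) - k) / length(v)
  })
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) return(NA_real_)
  mean(scores)
}

#' Detect table orientation
#'
#' A table with an explicit header section is horizontal. For headerless
#' tables the first body column is assumed to be a candidate label column:
#' when the per-row datatype homogeneity of the remaining body strictly
#' exceeds the per-column homogeneity, records run down the columns and
#' the table is vertical; ties (including all-numeric grids and
#' single-cell tables) go to horizontal.
#'
#' @param header,body Character matrices from [resolve_spans()].
#' @param strip_glyphs Passed to the datatype test (see [infer_datatype()]).
#' @return `"horizontal"` or `"vertical"`.
#' @export
detect_orientation <- function(header, body, strip_glyphs = FALSE) {
  if (nrow(header) > 0) return("horizontal")
  if (nrow(body) <= 1 || ncol(body) <= 1) return("horizontal")
  sub <- body[, -1, drop = FALSE]
  row_h <- homogeneity(sub, 1, strip_glyphs)
  col_h <- homogeneity(sub, 2, strip_glyphs)
  if (is.na(row_h) || is.na(col_h)) return("horizontal")
  if (row_h > col_h) "vertical" else "horizontal"
}

#' Transpose a grid
#'
#' Moves cell (i, j) to (j, i). Applied when a vertical table is
#' normalized; the first row of the transposed grid becomes the header.
#'
#' @param grid Character matrix.
#' @return The transposed character matrix.
#' @export
transpose_grid <- function(grid) {
  t(grid)
}

#' Merge a multi-row header into a single row of headings
#'
#' For each column, the distinct non-empty texts are concatenated from top
#' to bottom, joined by a single space; consecutive duplicates (which
#' arise from span replication) are skipped. A zero-row header yields
#' empty headings.
#'
#' @param header Character matrix (possibly 0 rows).
#' @param n_cols Number of headings to produce when the header is empty.
#' @return Character vector of raw headings, one per column.
#' @export
merge_header_rows <- function(header, n_cols = ncol(header)) {
  if (nrow(header) == 0) return(rep("", n_cols))
  out <- apply(header, 2, function(col) {
    col <- trimws(col)
    col <- col[nzchar(col)]
    if (length(col) == 0) return("")
    paste(rle(col)$values, collapse = " ")
  })
  out <- as.character(out)
  length(out) <- max(n_cols, length(out))
  out[is.na(out)] <- ""
  out
}

pad_cols <- function(m, n_cols) {
  if (ncol(m) < n_cols) {
    m <- cbind(m, matrix("", nrow(m), n_cols - ncol(m)))
  }
  m
}

#' Normalize a raw table
#'
#' Composes span resolution, orientation detection, optional transposition,
#' header merging and per-column datatype inference into a
#' `normalized_table`: a rectangular body grid under a single row of
#' headings, with every cell addressable by (row, column) indices.
#' `expanded_heading` starts equal to `raw_heading`; abbreviation
#' expansion ([expand_table()]) and column classification
#' ([classify_columns()]) update the header metadata later.
#'
#' @param raw A `raw_table` from [extract_tables()].
#' @param strip_glyphs Strip trailing footnote glyphs when inferring
#'   datatypes (see [infer_datatype()]).
#' @return An object of class `normalized_table` with fields `source`
#'   (article and table identifiers), `caption`, `footer`, `headers` (a
#'   data frame with `index`, `raw_heading`, `expanded_heading`,
#'   `datatype`, `category`), `body` (character matrix of expanded cell
#'   texts), `body_raw` (original texts) and `orientation`.
#' @export
normalize_table <- function(raw, strip_glyphs = FALSE) {
  stopifnot(inherits(raw, "raw_table"))
  g <- resolve_spans(raw$header_cells, raw$body_cells)
  orientation <- detect_orientation(g$header, g$body, strip_glyphs)
  if (orientation == "vertical") {
    flipped <- transpose_grid(g$body)
    header <- flipped[1, , drop = FALSE]
    body <- flipped[-1, , drop = FALSE]
    orientation <- "vertical-transposed"
  } else {
    header <- g$header
    body <- g$body
  }
  n_cols <- max(ncol(header), ncol(body), 0L)
  header <- pad_cols(header, n_cols)
  body <- pad_cols(body, n_cols)

  headings <- merge_header_rows(header, n_cols)
  datatypes <- if (n_cols > 0) {
    vapply(seq_len(n_cols), function(j) {
      infer_datatype(body[, j], strip_glyphs = strip_glyphs)
    }, character(1))
  } else {
    character(0)
  }

  headers <- data.frame(
    index = seq_len(n_cols) - 1L,
    raw_heading = headings,
    expanded_heading = headings,
    datatype = datatypes,
    category = rep("unclassified", n_cols),
    stringsAsFactors = FALSE)

  structure(
    list(source = list(article_id = raw$article_id %||% "",
                       table_id = raw$table_id, label = raw$label),
         caption = raw$caption, footer = raw$footer,
         headers = headers, body = body, body_raw = body,
         orientation = orientation, strip_glyphs = strip_glyphs),
    class = "normalized_table")
}

#' @export
print.normalized_table <- function(x, ...) {
  cat("<normalized_table> ", x$source$article_id, " / ", x$source$table_id,
      " [", x$orientation, "]\n", sep = "")
  cat("  ", nrow(x$body), " rows x ", ncol(x$body), " columns\n", sep = "")
  if (nrow(x$headers) > 0) {
    cat("  headings: ", paste(x$headers$expanded_heading, collapse = " | "),
        "\n", sep = "")
    cat("  datatypes: ", paste(x$headers$datatype, collapse = ", "),
        "\n", sep = "")
    if (any(x$headers$category != "unclassified")) {
      cat("  categories: ", paste(x$headers$category, collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' Dump a normalized table to TSV for inspection
#'
#' Writes the expanded header row first, then the body grid,
#' tab-separated. Debugging aid; not part of the persisted outputs.
#'
#' @param table A `normalized_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_normalized_tsv <- function(table, path) {
  stopifnot(inherits(table, "normalized_table"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(table$headers$expanded_heading, collapse = "\t"), con)
  if (nrow(table$body) > 0) {
    writeLines(apply(table$body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}
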