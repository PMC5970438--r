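# Trait-table filtering, column classification into descriptor /
# property / value, and QTL statement extraction.

#' Default trait-table filter keywords
#'
#' Whole-word, case-insensitive keywords matched against the table
#' subject (caption + headings + footer) to decide whether a table
#' carries trait/QTL content.
#'
#' @return Character vector of keywords.
#' @export
default_keywords <- function() {
  c("trait", "qtl", "phenotype", "phenotypic",
    "quantitative trait locus", "quantitative trait loci")
}

# Keywords that, found in a column heading, mark a descriptor column.
descriptor_heading_keywords <- c("trait", "phenotype", "qtl")

# Whole-word keyword pattern tolerating a plural "s"/"es" suffix, so that
# "QTLs" and "traits" hit the keywords "qtl" and "trait".
keyword_pattern <- function(kw) {
  paste0("(?<![\\p{L}\\p{N}])", regex_quote(kw),
         "(?:s|es)?(?![\\p{L}\\p{N}])")
}

#' Derive the subject of a table
#'
#' The subject is the space-separated concatenation of the caption, all
#' expanded column headings and the footer; it is the text the
#' trait-table keyword filter operates on.
#'
#' @param table A `normalized_table` (abbreviations expanded, so the
#'   subject carries the expansions too).
#' @return A single string.
#' @export
table_subject <- function(table) {
  stopifnot(inherits(table, "normalized_table"))
  parts <- c(table$caption, table$headers$expanded_heading, table$footer)
  paste(parts[nzchar(parts)], collapse = " ")
}

#' Decide whether a subject describes a trait table
#'
#' Case-insensitive whole-word matching of each keyword against the
#' subject; the decision records every keyword that hit. Adding keywords
#' can only turn a negative decision positive (monotonicity).
#'
#' @param subject Table subject text (see [table_subject()]).
#' @param keywords Non-empty character vector of keywords.
#' @return A list with `is_trait_table` (logical) and `matched_keywords`
#'   (character vector of the keywords that hit).
#' @export
is_trait_table <- function(subject, keywords = default_keywords()) {
  stopifnot(length(keywords) > 0)
  hits <- keywords[vapply(keywords, function(kw) {
    grepl(keyword_pattern(kw), subject, perl = TRUE, ignore.case = TRUE)
  }, logical(1))]
  list(is_trait_table = length(hits) > 0, matched_keywords = unname(hits))
}

# Trait-table decision for a whole table, recording where each keyword
# hit (caption / heading / footer).
decide_trait_table <- function(table, keywords = default_keywords()) {
  stopifnot(inherits(table, "normalized_table"))
  parts <- list(caption = table$caption,
                heading = paste(table$headers$expanded_heading,
                                collapse = " "),
                footer = table$footer)
  hits <- list()
  for (src in names(parts)) {
    d <- is_trait_table(paste0(" ", parts[[src]], " "), keywords)
    for (kw in d$matched_keywords) {
      hits[[length(hits) + 1L]] <- list(keyword = kw, source = src)
    }
  }
  list(is_trait_table = length(hits) > 0, matched_keywords = hits)
}

heading_has_descriptor_keyword <- function(heading) {
  any(vapply(descriptor_heading_keywords, function(kw) {
    grepl(keyword_pattern(kw), heading, perl = TRUE, ignore.case = TRUE)
  }, logical(1)))
}

#' Classify table columns into descriptor, property and value
#'
#' Applies the three-category scheme: numeric columns are trait values
#' (a statistical-ontology annotation of the heading is attempted);
#' alphanumeric columns whose heading or cells match a phenotypic
#' dictionary, or whose heading contains a trait/phenotype/QTL keyword,
#' are trait descriptors; remaining alphanumeric columns matching
#' chemical, genotypic or marker dictionaries are trait properties; and
#' anything else stays unclassified (treated as a property, without
#' concept annotation, during statement extraction).
#'
#' All concept matches found in body cells are recorded in the
#' `"cell_concepts"` attribute with their (row, column) coordinates.
#'
#' @param table A `normalized_table` (after [expand_table()]).
#' @param index A `term_index`.
#' @return The table with `headers$category` set and cell-level concept
#'   matches attached.
#' @export
classify_columns <- function(table, index) {
  stopifnot(inherits(table, "normalized_table"))
  n_cols <- nrow(table$headers)
  concepts <- list()
  note_matches <- function(m, row, col) {
    if (nrow(m) == 0) return()
    m$row <- row
    m$col <- col
    concepts[[length(concepts) + 1L]] <<- m
  }
  for (j in seq_len(n_cols)) {
    heading <- table$headers$expanded_heading[j]
    if (table$headers$datatype[j] == "numeric") {
      table$headers$category[j] <- "value"
      hm <- annotate(heading, index)
      hm <- hm[hm$category == "statistical", , drop = FALSE]
      if (nrow(hm) > 0) {
        table$headers$heading_term_id <- table$headers$heading_term_id %||%
          rep(NA_character_, n_cols)
        table$headers$heading_term_id[j] <- hm$term_id[1]
      }
      next
    }
    heading_matches <- annotate(heading, index)
    cells <- table$body[, j]
    cell_matches <- lapply(seq_along(cells), function(r) {
      if (!nzchar(cells[r])) return(empty_matches())
      annotate(cells[r], index)
    })
    for (r in seq_along(cell_matches)) {
      note_matches(cell_matches[[r]], r - 1L, j - 1L)
    }
    all_cats <- c(heading_matches$category,
                  unlist(lapply(cell_matches, `[[`, "category")))
    if ("phenotypic" %in% all_cats ||
        heading_has_descriptor_keyword(heading)) {
      table$headers$category[j] <- "descriptor"
    } else if (any(c("chemical", "genotypic", "marker") %in% all_cats)) {
      table$headers$category[j] <- "property"
    } else {
      table$headers$category[j] <- "unclassified"
    }
  }
  cell_concepts <- if (length(concepts) > 0) {
    out <- do.call(rbind, concepts)
    rownames(out) <- NULL
    out
  } else {
    cbind(empty_matches(), data.frame(row = integer(0), col = integer(0)))
  }
  attr(table, "cell_concepts") <- cell_concepts
  table
}

best_cell_concept <- function(cell_concepts, row, col) {
  m <- cell_concepts[cell_concepts$row == row & cell_concepts$col == col, ,
                     drop = FALSE]
  if (nrow(m) == 0) return(NULL)
  m[1, , drop = FALSE]
}

#' Extract QTL statements from a classified trait table
#'
#' The leftmost descriptor column supplies the statement subject; one
#' statement is emitted per body row with a non-empty descriptor cell.
#' Every other column with a non-empty cell contributes a
#' predicate-object pair (predicate = expanded heading, object = expanded
#' cell value), with concept annotations attached where available.
#' A table without any descriptor column yields no statements (with a
#' message, not an error).
#'
#' @param table A `normalized_table` after [classify_columns()].
#' @return List of `qtl_statement` objects, each with `article_id`,
#'   `table_id`, `row_index` (0-based), `subject_text`,
#'   `subject_term_id` (`NA` when unannotated) and `pairs` (data frame
#'   with `predicate`, `object_text`, `object_term_id`,
#'   `column_category`).
#' @export
extract_statements <- function(table) {
  stopifnot(inherits(table, "normalized_table"))
  desc_cols <- which(table$headers$category == "descriptor")
  if (length(desc_cols) == 0) {
    message("no descriptor column in ", table$source$table_id,
            "; no statements extracted")
    return(list())
  }
  dc <- desc_cols[1]
  cell_concepts <- attr(table, "cell_concepts") %||%
    cbind(empty_matches(), data.frame(row = integer(0), col = integer(0)))
  statements <- list()
  for (r in seq_len(nrow(table$body))) {
    subject_text <- trimws(table$body[r, dc])
    if (!nzchar(subject_text)) next
    subj <- best_cell_concept(cell_concepts, r - 1L, dc - 1L)
    other <- setdiff(seq_len(ncol(table$body)), dc)
    keep <- other[nzchar(trimws(table$body[r, other]))]
    pairs <- data.frame(
      predicate = table$headers$expanded_heading[keep],
      object_text = trimws(table$body[r, keep]),
      object_term_id = vapply(keep, function(j) {
        m <- best_cell_concept(cell_concepts, r - 1L, j - 1L)
        if (is.null(m)) NA_character_ else m$term_id
      }, character(1)),
      column_category = ifelse(
        table$headers$category[keep] == "value", "value", "property"),
      stringsAsFactors = FALSE)
    statements[[length(statements) + 1L]] <- structure(
      list(article_id = table$source$article_id,
           table_id = table$source$table_id,
           row_index = r - 1L,
           subject_text = subject_text,
           subject_term_id = if (is.null(subj)) NA_character_ else
             subj$term_id,
           pairs = pairs),
      class = "qtl_statement")
  }
  statements
}

#' @export
print.qtl_statement <- function(x, ...) {
  cat("<qtl_statement> ", x$article_id, "/", x$table_id, " row ",
      x$row_index, "\n", sep = "")
  cat("  subject: ", x$subject_text,
      if (!is.na(x$subject_term_id)) paste0(" [", x$subject_term_id, "]"),
      "\n", sep = "")
  for (k in seq_len(nrow(x$pairs))) {
    cat("  - ", x$pairs$predicate[k], " = ", x$pairs$object_text[k],
        if (!is.na(x$pairs$object_term_id[k]))
          paste0(" [", x$pairs$object_term_id[k], "]"),
        "\n", sep = "")
  }
  invisible(x)
}

#' Merge statements that describe the same trait
#'
#' Groups an article's statements by subject concept identifier when the
#' subject was annotated, and by the normalized subject text otherwise,
#' so that the same trait reported across several tables (possibly under
#' an abbreviation in one of them) collapses into one group. The groups
#' partition the input.
#'
#' @param statements List of `qtl_statement`s from one article (or a
#'   whole corpus; the key includes no article component, so
#'   cross-article merging is the caller's choice).
#' @return Named list of statement groups, keyed by term id or
#'   normalized subject text.
#' @export
merge_statements <- function(statements) {
  keys <- vapply(statements, function(s) {
    if (!is.na(s$subject_term_id)) s$subject_term_id else
      normalize_term(s$subject_text)
  }, character(1))
  split(statements, keys)
}
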