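# Schwartz-Hearst abbreviation detection and expansion.
#
# The matcher pairs a parenthesized short form with the shortest adjacent
# long form that contains the short form's characters in order, with the
# first character of the short form anchored at the start of a word.

max_long_words <- function(short_form) {
  n <- nchar(short_form)
  min(n + 5L, 2L * n)
}

valid_short_form <- function(sf) {
  n <- nchar(sf)
  n >= 2 && n <= 10 &&
    grepl("\\p{L}", sf, perl = TRUE) &&
    grepl("^[\\p{L}\\p{N}]", sf, perl = TRUE)
}

last_n_words <- function(text, n) {
  words <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  words <- words[nzchar(words)]
  if (length(words) > n) words <- words[(length(words) - n + 1):length(words)]
  paste(words, collapse = " ")
}

count_words <- function(text) {
  words <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  sum(nzchar(words))
}

#' Find the best long form for a short form (Schwartz-Hearst matcher)
#'
#' Scans the window right to left, matching each alphanumeric character of
#' the short form case-insensitively at its rightmost feasible position;
#' the short form's first character must match at the start of a word.
#' The returned long form is the shortest suffix of the window satisfying
#' the match (starting at the word where the first character matched), or
#' `NULL` when no match exists.
#'
#' @param short_form Candidate short form (already validated).
#' @param window Text immediately preceding the parenthesis, truncated by
#'   the caller to at most `min(nchar(short) + 5, 2 * nchar(short))` words.
#' @return The long form string, or `NULL`.
#' @export
best_long_form <- function(short_form, window) {
  if (!nzchar(window)) return(NULL)
  s_chars <- strsplit(tolower(short_form), "")[[1]]
  l_chars <- strsplit(tolower(window), "")[[1]]
  si <- length(s_chars)
  li <- length(l_chars)
  while (si >= 1) {
    ch <- s_chars[si]
    if (!is_word_char(ch)) {
      si <- si - 1L
      next
    }
    repeat {
      if (li < 1) return(NULL)
      hit <- identical(l_chars[li], ch)
      # the first character must sit at a word start
      bad_start <- si == 1L && li > 1L && is_word_char(l_chars[li - 1L])
      if (hit && !bad_start) break
      li <- li - 1L
    }
    li <- li - 1L
    si <- si - 1L
  }
  lf <- trimws(substring(window, li + 1L, nchar(window)))
  if (!nzchar(lf)) return(NULL)
  if (nchar(lf) < nchar(short_form)) return(NULL)
  if (identical(tolower(lf), tolower(short_form))) return(NULL)
  lf
}

empty_pairs <- function() {
  data.frame(short_form = character(0), long_form = character(0),
             source = character(0), stringsAsFactors = FALSE)
}

#' Find abbreviation pairs in a text passage
#'
#' Scans for parenthesized candidates in both definition patterns,
#' `long form (short form)` and `short form (long form)`. Candidate short
#' forms must be 2-10 characters, contain a letter and start with an
#' alphanumeric character; long forms are limited to
#' `min(nchar(short) + 5, 2 * nchar(short))` words. Each validated pair is
#' emitted once.
#'
#' @param text A passage (caption, footer, cell or body paragraph).
#' @param source Location tag recorded with each pair: one of `"caption"`,
#'   `"footer"`, `"body_paragraph"`, `"cell"`.
#' @return Data frame with columns `short_form`, `long_form`, `source`.
#' @export
find_pairs <- function(text, source = "body_paragraph") {
  if (!nzchar(text) || !grepl("(", text, fixed = TRUE)) return(empty_pairs())
  m <- gregexpr("\\(([^()]*)\\)", text)[[1]]
  if (m[1] == -1) return(empty_pairs())
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  shorts <- character(0)
  longs <- character(0)
  for (k in seq_along(starts)) {
    inner <- trimws(substring(text, starts[k] + 1L, starts[k] + lens[k] - 2L))
    before <- substring(text, 1L, starts[k] - 1L)
    if (valid_short_form(inner)) {
      # pattern: long form (short form)
      window <- last_n_words(before, max_long_words(inner))
      lf <- best_long_form(inner, window)
      if (!is.null(lf)) {
        shorts <- c(shorts, inner)
        longs <- c(longs, lf)
      }
    } else {
      # pattern: short form (long form)
      cand <- sub("[[:punct:]]+$", "",
                  last_n_words(trimws(before), 1L))
      if (valid_short_form(cand) &&
          count_words(inner) <= max_long_words(cand)) {
        lf <- best_long_form(cand, inner)
        if (!is.null(lf)) {
          shorts <- c(shorts, cand)
          longs <- c(longs, lf)
        }
      }
    }
  }
  if (length(shorts) == 0) return(empty_pairs())
  out <- data.frame(short_form = shorts, long_form = longs,
                    source = source, stringsAsFactors = FALSE)
  out[!duplicated(out[c("short_form", "long_form")]), , drop = FALSE]
}

# Source precedence when one short form maps to several long forms:
# definitions nearer the table win.
abbrev_source_rank <- c(cell = 1, footer = 2, caption = 3, body_paragraph = 4)

#' Collect all abbreviation pairs defined in an article
#'
#' Runs [find_pairs()] over every table caption, footer and cell and every
#' body paragraph of the article, deduplicates by exact
#' (short form, long form) pair, and — when one short form maps to several
#' long forms — keeps the pair found nearest the tables
#' (cell > footer > caption > body paragraph).
#'
#' @param doc An `article_doc`.
#' @param tables List of `normalized_table`s from the same article.
#' @return Data frame with columns `short_form`, `long_form`, `source`.
#' @export
collect_article_abbreviations <- function(doc, tables = list()) {
  stopifnot(inherits(doc, "article_doc"))
  found <- list()
  for (tab in tables) {
    if (nzchar(tab$caption)) {
      found[[length(found) + 1L]] <- find_pairs(tab$caption, "caption")
    }
    if (nzchar(tab$footer)) {
      found[[length(found) + 1L]] <- find_pairs(tab$footer, "footer")
    }
    cells <- as.vector(tab$body_raw)
    cells <- cells[nzchar(cells) & grepl("(", cells, fixed = TRUE)]
    for (cell in cells) {
      found[[length(found) + 1L]] <- find_pairs(cell, "cell")
    }
  }
  for (p in doc$body_paragraphs) {
    found[[length(found) + 1L]] <- find_pairs(p, "body_paragraph")
  }
  if (length(found) == 0) return(empty_pairs())
  pairs <- do.call(rbind, found)
  if (nrow(pairs) == 0) return(pairs)
  pairs <- pairs[!duplicated(pairs[c("short_form", "long_form")]), ,
                 drop = FALSE]
  # conflict resolution: order by precedence, keep first per short form
  pairs <- pairs[order(abbrev_source_rank[pairs$source]), , drop = FALSE]
  pairs <- pairs[!duplicated(pairs$short_form), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

replace_tokens <- function(x, short_form, long_form) {
  gsub(word_pattern(short_form), long_form, x, perl = TRUE)
}

#' Expand abbreviations in a normalized table
#'
#' Replaces every whole-token occurrence of a short form in the headings
#' and in the cells of alphanumeric columns by its long form. Tokens are
#' bounded by non-alphanumeric characters, so marker IDs such as `CT99`
#' are never corrupted and numeric-column cells are never altered.
#' Original raw cell texts are retained in `body_raw`; applied expansions
#' are recorded in the `"expansions"` attribute for provenance.
#'
#' @param table A `normalized_table`.
#' @param pairs Data frame of abbreviation pairs from
#'   [collect_article_abbreviations()].
#' @return The table with `expanded_heading` and `body` updated.
#' @export
expand_table <- function(table, pairs) {
  stopifnot(inherits(table, "normalized_table"))
  if (is.null(pairs) || nrow(pairs) == 0) return(table)
  # longer short forms first so overlapping candidates cannot clobber
  pairs <- pairs[order(-nchar(pairs$short_form)), , drop = FALSE]
  applied <- character(0)
  alnum_cols <- which(table$headers$datatype == "alphanumeric")
  for (k in seq_len(nrow(pairs))) {
    sf <- pairs$short_form[k]
    lf <- pairs$long_form[k]
    pat <- word_pattern(sf)
    hit <- FALSE
    touched <- grepl(pat, table$headers$expanded_heading, perl = TRUE)
    if (any(touched)) {
      table$headers$expanded_heading <- replace_tokens(
        table$headers$expanded_heading, sf, lf)
      hit <- TRUE
    }
    for (j in alnum_cols) {
      col <- table$body[, j]
      sel <- grepl(pat, col, perl = TRUE)
      if (any(sel)) {
        table$body[sel, j] <- replace_tokens(col[sel], sf, lf)
        hit <- TRUE
      }
    }
    if (hit) applied <- c(applied, sf)
  }
  attr(table, "expansions") <- applied
  table
}
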