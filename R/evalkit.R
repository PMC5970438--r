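# Precision/recall scoring at the four evaluation levels:
# trait table, abbreviation, entity, statement.

eval_levels <- c("trait_table", "abbreviation", "entity", "statement")

#' Compute precision and recall from confusion counts
#'
#' Precision is `100 * tp / (tp + fp)` and recall `100 * tp / (tp + fn)`,
#' rounded half-up to two decimals for display. An undefined denominator
#' yields `NA` (printed as "undefined"), never 0 or 100.
#'
#' @param tp,fp,fn Non-negative confusion counts.
#' @param tn Optional true-negative count (carried, not used).
#' @param level Optional evaluation level tag.
#' @return An `eval_result` with fields `precision`, `recall` (percent,
#'   `NA` when undefined) and the input counts.
#' @export
score <- function(tp, fp, fn, tn = NA_integer_, level = NA_character_) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) round_half_up(100 * tp / (tp + fp), 2) else
    NA_real_
  recall <- if (tp + fn > 0) round_half_up(100 * tp / (tp + fn), 2) else
    NA_real_
  structure(list(precision = precision, recall = recall,
                 tp = tp, fp = fp, fn = fn, tn = tn, level = level),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat("<eval_result>",
      if (!is.na(x$level)) paste0(" [", x$level, "]"), "\n", sep = "")
  cat("  TP=", x$tp, " FP=", x$fp, " FN=", x$fn,
      if (!is.na(x$tn)) paste0(" TN=", x$tn), "\n", sep = "")
  cat("  precision ", fmt(x$precision), ", recall ", fmt(x$recall),
      "\n", sep = "")
  invisible(x)
}

KEY_SEP <- "\x1f"

mk_key <- function(...) {
  do.call(paste, c(list(...), sep = KEY_SEP))
}

predicted_keys <- function(result, level) {
  switch(
    level,
    trait_table = {
      d <- result$trait_decisions
      d <- d[d$is_trait_table, , drop = FALSE]
      mk_key(d$article_id, d$table_id)
    },
    abbreviation = {
      a <- result$abbreviations
      mk_key(a$article_id, a$short_form, normalize_term(a$long_form))
    },
    entity = {
      cc <- result$cell_concepts
      mk_key(cc$article_id, cc$table_id, cc$row, cc$col, cc$term_id)
    },
    statement = {
      vapply(result$statements, function(s) {
        mk_key(s$article_id, s$table_id, s$row_index,
               normalize_term(s$subject_text))
      }, character(1))
    },
    stop("unknown evaluation level: ", level, call. = FALSE))
}

gold_keys <- function(gold, level) {
  out <- lapply(gold, function(g) {
    switch(
      level,
      trait_table = if (length(g$trait_tables) > 0) {
        mk_key(g$pmcid, g$trait_tables)
      } else character(0),
      abbreviation = if (nrow(g$abbreviations) > 0) {
        mk_key(g$pmcid, g$abbreviations$short_form,
               normalize_term(g$abbreviations$long_form))
      } else character(0),
      entity = if (nrow(g$entities) > 0) {
        mk_key(g$pmcid, g$entities$table_id, g$entities$row,
               g$entities$col, g$entities$term_id)
      } else character(0),
      statement = if (nrow(g$statements) > 0) {
        mk_key(g$pmcid, g$statements$table_id, g$statements$row,
               normalize_term(g$statements$subject))
      } else character(0))
  })
  unlist(out, use.names = FALSE)
}

#' Compare predictions against gold at one evaluation level
#'
#' Matching keys per level: trait table by (article, table id);
#' abbreviation by (article, short form, normalized long form); entity by
#' (article, table, cell coordinates, term CURIE); statement by (article,
#' table, row, normalized subject). `tp` counts the intersection of the
#' predicted and gold key sets, `fp` the predictions outside gold, `fn`
#' the gold keys missed.
#'
#' @param result A `mining_result` for the corpus.
#' @param gold Gold annotations from [read_gold()] or
#'   [generate_corpus()]`$gold`.
#' @param level One of `"trait_table"`, `"abbreviation"`, `"entity"`,
#'   `"statement"`.
#' @return An `eval_result` (see [score()]).
#' @export
compare_results <- function(result, gold, level) {
  level <- match.arg(level, eval_levels)
  stopifnot(inherits(result, "mining_result"))
  pred_articles <- result$articles$article_id
  gold_articles <- vapply(gold, `[[`, character(1), "pmcid")
  if (length(pred_articles) > 0 && length(gold_articles) > 0 &&
      length(intersect(pred_articles, gold_articles)) == 0) {
    stop("predicted and gold annotations refer to different corpora",
         call. = FALSE)
  }
  pred <- unique(predicted_keys(result, level))
  gld <- unique(gold_keys(gold, level))
  tp <- length(intersect(pred, gld))
  score(tp = tp, fp = length(setdiff(pred, gld)),
        fn = length(setdiff(gld, pred)), level = level)
}

#' Four-level evaluation report
#'
#' Runs [compare_results()] at every level and assembles a table of
#' confusion counts with precision and recall (percent, `NA` when
#' undefined).
#'
#' @inheritParams compare_results
#' @param path Optional path; when given, the report is also written as
#'   TSV.
#' @return Data frame with columns `level`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`.
#' @export
eval_report <- function(result, gold, path = NULL) {
  rows <- lapply(eval_levels, function(lv) {
    r <- compare_results(result, gold, lv)
    data.frame(level = lv, tp = r$tp, fp = r$fp, fn = r$fn,
               precision = r$precision, recall = r$recall,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  report
}
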