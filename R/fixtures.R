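# Synthetic JATS corpus generator with gold annotations.
#
# Articles emulate the structural variety of real full-text tables:
# horizontal and vertical orientation, nested multi-row headers with
# row/column spans, in-article abbreviation definitions and footnote
# glyphs on numeric cells. Trait tables draw their subjects from the
# bundled mini-dictionary so every pipeline stage can be scored against
# the planted gold annotations offline.

#' Specify a synthetic corpus
#'
#' The defaults are the package's reference study conditions: ten
#' articles of two to three tables, 60% of them trait tables, with
#' vertical orientation in 30% and nested headers in 30% of the trait
#' tables, and half of the multi-word trait terms abbreviated through a
#' well-formed in-article definition. Footnote glyphs and malformed
#' definitions are off by default; turning them on exercises the
#' documented legacy failure modes.
#'
#' @param n_articles Number of articles.
#' @param tables_per_article Integer range (length-2 vector) of tables
#'   per article.
#' @param trait_table_fraction Probability a table is a trait table.
#' @param orientation_mix Probability a trait table is emitted vertically
#'   (records down the columns, no header section).
#' @param nested_header_prob Probability a horizontal trait table gets a
#'   two-row nested header with spans.
#' @param abbreviation_prob Probability a multi-word trait term appears
#'   abbreviated, with its definition planted in the table footer or a
#'   body paragraph.
#' @param footnote_glyph_prob Probability a numeric cell gains a trailing
#'   `**` mark.
#' @param malformed_abbrev If `TRUE`, definitions are written in an
#'   unsupported dash format instead of `long form (short form)`.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_articles = 10L,
                        tables_per_article = c(2L, 3L),
                        trait_table_fraction = 0.6,
                        orientation_mix = 0.3,
                        nested_header_prob = 0.3,
                        abbreviation_prob = 0.5,
                        footnote_glyph_prob = 0,
                        malformed_abbrev = FALSE,
                        seed = 42L) {
  probs <- c(trait_table_fraction, orientation_mix, nested_header_prob,
             abbreviation_prob, footnote_glyph_prob)
  stopifnot(n_articles >= 1, length(tables_per_article) == 2,
            all(tables_per_article >= 1),
            all(probs >= 0 & probs <= 1))
  structure(
    list(n_articles = as.integer(n_articles),
         tables_per_article = as.integer(tables_per_article),
         trait_table_fraction = trait_table_fraction,
         orientation_mix = orientation_mix,
         nested_header_prob = nested_header_prob,
         abbreviation_prob = abbreviation_prob,
         footnote_glyph_prob = footnote_glyph_prob,
         malformed_abbrev = isTRUE(malformed_abbrev),
         seed = as.integer(seed)),
    class = "corpus_spec")
}

#' @export
print.corpus_spec <- function(x, ...) {
  cat("<corpus_spec> ", x$n_articles, " articles, ",
      x$tables_per_article[1], "-", x$tables_per_article[2],
      " tables each (seed ", x$seed, ")\n", sep = "")
  cat(sprintf(
    "  trait fraction %.2f, vertical %.2f, nested %.2f, abbrev %.2f, glyphs %.2f%s\n",
    x$trait_table_fraction, x$orientation_mix, x$nested_header_prob,
    x$abbreviation_prob, x$footnote_glyph_prob,
    if (x$malformed_abbrev) ", malformed definitions" else ""))
  invisible(x)
}

# Trait terms planted in synthetic tables; CURIEs as in the bundled
# mini-dictionary. Multi-word terms carry a conventional short form.
synthetic_traits <- function() {
  data.frame(
    label = c("fruit shape", "compound leaf", "anthocyanin content",
              "fructose content", "stem strength", "plant fresh weight",
              "ascorbic acid", "β-carotene", "pH", "fruit", "stem"),
    term_id = c("SP:0000038", "SP:0000177", "SP:0000016", "SP:0000386",
                "TO:0000051", "TO:0000442", "CHEBI:22652", "TO:000269",
                "SP:0000170", "SP:00000378", "SP:0000193"),
    short_form = c("FS", "CL", "AC", "FC", "SS", "PFW", "AsA",
                   "β-C", NA, NA, NA),
    stringsAsFactors = FALSE)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

cell_xml <- function(tag, text, rowspan = 1L, colspan = 1L) {
  attrs <- ""
  if (rowspan > 1) attrs <- paste0(attrs, sprintf(' rowspan="%d"', rowspan))
  if (colspan > 1) attrs <- paste0(attrs, sprintf(' colspan="%d"', colspan))
  sprintf("<%s%s>%s</%s>", tag, attrs, xml_escape(text), tag)
}

row_xml <- function(cells) {
  paste0("<tr>", paste(cells, collapse = ""), "</tr>")
}

table_wrap_xml <- function(id, label, caption, thead_rows, tbody_rows,
                           footer) {
  thead <- if (length(thead_rows) > 0) {
    paste0("<thead>", paste(thead_rows, collapse = ""), "</thead>")
  } else ""
  foot <- if (nzchar(footer)) {
    paste0("<table-wrap-foot><p>", xml_escape(footer),
           "</p></table-wrap-foot>")
  } else ""
  paste0(
    '<table-wrap id="', id, '"><label>', xml_escape(label), "</label>",
    "<caption><p>", xml_escape(caption), "</p></caption>",
    '<table frame="hsides" rules="groups">', thead,
    "<tbody>", paste(tbody_rows, collapse = ""), "</tbody></table>",
    foot, "</table-wrap>")
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One trait table plus its gold annotations. `registry` is an
# article-level environment tracking abbreviation definitions and the
# corpus-level marker list.
build_trait_table <- function(spec, tab_num, registry) {
  traits <- synthetic_traits()
  n_rows <- sample(2:4, 1)
  picked <- traits[sample(nrow(traits), n_rows), , drop = FALSE]

  vertical <- runif(1) < spec$orientation_mix
  nested <- !vertical && runif(1) < spec$nested_header_prob

  extra_defs <- character(0)
  display <- picked$label
  for (k in seq_len(n_rows)) {
    sf <- picked$short_form[k]
    lf <- picked$label[k]
    if (is.na(sf) || runif(1) >= spec$abbreviation_prob) next
    already <- registry$abbrevs[[sf]]
    if (is.null(already)) {
      registry$abbrevs[[sf]] <- lf
      def <- if (spec$malformed_abbrev) {
        sprintf("%s — %s", sf, lf)
      } else {
        sprintf("%s (%s)", lf, sf)
      }
      if (runif(1) < 0.5) {
        extra_defs <- c(extra_defs, def)
      } else {
        registry$body_defs <- c(
          registry$body_defs,
          sprintf("In this study %s was scored on the mapping population.",
                  def))
      }
      display[k] <- sf
    } else if (identical(already, lf)) {
      display[k] <- sf
    }
  }

  markers <- character(n_rows)
  for (k in seq_len(n_rows)) {
    registry$marker_n <- registry$marker_n + 1L
    markers[k] <- sprintf("TG%03d", registry$marker_n)
    registry$markers <- c(registry$markers, markers[k])
  }
  lod <- sprintf("%.1f", round(runif(n_rows, 1.5, 12), 1))
  if (spec$footnote_glyph_prob > 0) {
    starred <- runif(n_rows) < spec$footnote_glyph_prob
    lod[starred] <- paste0(lod[starred], "**")
  }
  chr <- as.character(sample(1:12, n_rows, replace = TRUE))

  caption <- "QTLs detected for plant quality traits"
  footer <- paste(extra_defs, collapse = "; ")

  if (vertical) {
    tbody <- list(
      row_xml(vapply(c("Trait", display), function(x) cell_xml("td", x),
                     character(1))),
      row_xml(vapply(c("Marker", markers), function(x) cell_xml("td", x),
                     character(1))),
      row_xml(vapply(c("LOD", lod), function(x) cell_xml("td", x),
                     character(1))),
      row_xml(vapply(c("Chr", chr), function(x) cell_xml("td", x),
                     character(1))))
    thead <- list()
    headings <- c("Trait", "Marker", "LOD", "Chr")
  } else if (nested) {
    thead <- list(
      row_xml(c(cell_xml("th", "Trait", rowspan = 2L),
                cell_xml("th", "Marker", rowspan = 2L),
                cell_xml("th", "QTL", colspan = 2L))),
      row_xml(c(cell_xml("th", "LOD"), cell_xml("th", "Chr"))))
    tbody <- lapply(seq_len(n_rows), function(k) {
      row_xml(c(cell_xml("td", display[k]), cell_xml("td", markers[k]),
                cell_xml("td", lod[k]), cell_xml("td", chr[k])))
    })
    headings <- c("Trait", "Marker", "QTL LOD", "QTL Chr")
  } else {
    thead <- list(row_xml(c(cell_xml("th", "Trait"),
                            cell_xml("th", "Marker"),
                            cell_xml("th", "LOD"),
                            cell_xml("th", "Chr"))))
    tbody <- lapply(seq_len(n_rows), function(k) {
      row_xml(c(cell_xml("td", display[k]), cell_xml("td", markers[k]),
                cell_xml("td", lod[k]), cell_xml("td", chr[k])))
    })
    headings <- c("Trait", "Marker", "LOD", "Chr")
  }

  id <- sprintf("Tab%d", tab_num)
  xml <- table_wrap_xml(id, sprintf("Table %d", tab_num), caption,
                        thead, tbody, footer)

  marker_ids <- vapply(markers, function(m) {
    sprintf("SGN-M%s", sub("^TG", "", m))
  }, character(1))
  gold <- list(
    table_id = id,
    entities = rbind(
      data.frame(table_id = id, row = seq_len(n_rows) - 1L, col = 0L,
                 term_id = picked$term_id, stringsAsFactors = FALSE),
      data.frame(table_id = id, row = seq_len(n_rows) - 1L, col = 1L,
                 term_id = marker_ids, stringsAsFactors = FALSE)),
    statements = data.frame(table_id = id, row = seq_len(n_rows) - 1L,
                            subject = picked$label,
                            stringsAsFactors = FALSE),
    headings = headings)
  list(xml = xml, gold = gold)
}

build_filler_table <- function(tab_num) {
  kind <- sample(c("primers", "locations"), 1)
  id <- sprintf("Tab%d", tab_num)
  if (kind == "primers") {
    n <- sample(2:4, 1)
    thead <- list(row_xml(c(cell_xml("th", "Primer"),
                            cell_xml("th", "Sequence"),
                            cell_xml("th", "Tm"))))
    tbody <- lapply(seq_len(n), function(k) {
      row_xml(c(cell_xml("td", sprintf("P%02d", k)),
                cell_xml("td", random_sequence(12)),
                cell_xml("td", sprintf("%.1f", runif(1, 52, 62)))))
    })
    caption <- "List of primers used in this study"
  } else {
    n <- sample(2:3, 1)
    thead <- list(row_xml(c(cell_xml("th", "Location"),
                            cell_xml("th", "Year"),
                            cell_xml("th", "Season"))))
    tbody <- lapply(seq_len(n), function(k) {
      row_xml(c(cell_xml("td", sprintf("Site %d", k)),
                cell_xml("td", as.character(sample(2008:2015, 1))),
                cell_xml("td", sample(c("spring", "autumn"), 1))))
    })
    caption <- "Field locations and growing seasons"
  }
  table_wrap_xml(id, sprintf("Table %d", tab_num), caption, thead, tbody, "")
}

build_article <- function(spec, article_num, marker_start) {
  pmcid <- sprintf("PMC9%06d", article_num)
  registry <- new.env(parent = emptyenv())
  registry$abbrevs <- list()
  registry$body_defs <- character(0)
  registry$markers <- character(0)
  registry$marker_n <- marker_start

  n_tables <- sample(seq(spec$tables_per_article[1],
                         spec$tables_per_article[2]), 1)
  is_trait <- runif(n_tables) < spec$trait_table_fraction
  if (!any(is_trait)) is_trait[1] <- TRUE

  wraps <- character(n_tables)
  gold_entities <- list()
  gold_statements <- list()
  trait_ids <- character(0)
  for (t in seq_len(n_tables)) {
    if (is_trait[t]) {
      built <- build_trait_table(spec, t, registry)
      wraps[t] <- built$xml
      trait_ids <- c(trait_ids, built$gold$table_id)
      gold_entities[[length(gold_entities) + 1L]] <- built$gold$entities
      gold_statements[[length(gold_statements) + 1L]] <- built$gold$statements
    } else {
      wraps[t] <- build_filler_table(t)
    }
  }

  paras <- c(
    "Marker analysis was carried out on the mapping population across two growing seasons.",
    registry$body_defs,
    "Linkage maps were constructed from the genotyping data of both parents.")
  body <- paste0(
    "<sec><title>Results</title>",
    paste(vapply(paras, function(p) paste0("<p>", xml_escape(p), "</p>"),
                 character(1)), collapse = ""),
    paste(wraps, collapse = ""), "</sec>")
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<article xmlns:xlink="http://www.w3.org/1999/xlink">',
    "<front><article-meta>",
    '<article-id pub-id-type="pmcid">', pmcid, "</article-id>",
    "<title-group><article-title>Mapping study ", article_num,
    " on fruit and plant development</article-title></title-group>",
    "</article-meta></front><body>", body, "</body></article>")

  abbrev_gold <- if (length(registry$abbrevs) > 0) {
    data.frame(short_form = names(registry$abbrevs),
               long_form = unlist(registry$abbrevs, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(short_form = character(0), long_form = character(0),
               stringsAsFactors = FALSE)
  }
  entities <- if (length(gold_entities) > 0) {
    do.call(rbind, gold_entities)
  } else {
    data.frame(table_id = character(0), row = integer(0), col = integer(0),
               term_id = character(0), stringsAsFactors = FALSE)
  }
  statements <- if (length(gold_statements) > 0) {
    do.call(rbind, gold_statements)
  } else {
    data.frame(table_id = character(0), row = integer(0),
               subject = character(0), stringsAsFactors = FALSE)
  }
  list(pmcid = pmcid, xml = xml,
       gold = list(pmcid = pmcid, trait_tables = trait_ids,
                   abbreviations = abbrev_gold, entities = entities,
                   statements = statements),
       markers = registry$markers,
       marker_n = registry$marker_n)
}

#' Generate a synthetic JATS corpus with gold annotations
#'
#' Deterministic given the spec's seed: the same spec yields
#' byte-identical XML. When `dir` is given, one `<PMCID>.xml` file per
#' article, a `gold.json` annotations file and a synthetic marker
#' dictionary (`markers_synthetic.tsv`, loadable with [load_tsv()] as
#' source `"SGN-markers"`) are written there.
#'
#' @param spec A `corpus_spec`.
#' @param dir Optional output directory (created if missing).
#' @return Invisibly, a list with `articles` (each with `pmcid`, `xml`,
#'   `gold`), `gold` (per-article gold annotations) and `marker_entries`
#'   (dictionary entries for the planted markers).
#' @export
generate_corpus <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "corpus_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  articles <- list()
  all_markers <- character(0)
  marker_n <- 100L
  for (a in seq_len(spec$n_articles)) {
    built <- build_article(spec, a, marker_n)
    marker_n <- built$marker_n
    all_markers <- c(all_markers, built$markers)
    articles[[a]] <- built[c("pmcid", "xml", "gold")]
  }

  marker_entries <- lapply(all_markers, function(m) {
    new_entry(sprintf("SGN-M%s", sub("^TG", "", m)), m, character(0),
              "SGN-markers", "marker")
  })
  gold <- lapply(articles, `[[`, "gold")

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (art in articles) {
      writeLines(art$xml, file.path(dir, paste0(art$pmcid, ".xml")),
                 useBytes = TRUE)
    }
    jsonlite::write_json(
      list(articles = lapply(gold, function(g) {
        list(pmcid = g$pmcid, trait_tables = g$trait_tables,
             abbreviations = g$abbreviations, entities = g$entities,
             statements = g$statements)
      })),
      file.path(dir, "gold.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    writeLines(vapply(marker_entries, function(e) {
      paste(e$term_id, e$label, sep = "\t")
    }, character(1)), file.path(dir, "markers_synthetic.tsv"),
    useBytes = TRUE)
  }

  invisible(list(articles = articles, gold = gold,
                 marker_entries = marker_entries, spec = spec))
}

#' Read a gold annotations file
#'
#' @param path Path to a `gold.json` written by [generate_corpus()].
#' @return List of per-article gold annotations.
#' @export
read_gold <- function(path) {
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = TRUE)
  arts <- parsed$articles
  if (is.data.frame(arts)) {
    arts <- lapply(seq_len(nrow(arts)), function(i) {
      as.list(arts[i, , drop = FALSE])
    })
  }
  lapply(arts, function(g) {
    fix_df <- function(x, cols) {
      if (is.list(x) && !is.data.frame(x)) x <- x[[1]]
      if (is.null(x) || (is.data.frame(x) && nrow(x) == 0) ||
          length(x) == 0) {
        out <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                      cols), stringsAsFactors = FALSE)
        return(out)
      }
      as.data.frame(x, stringsAsFactors = FALSE)
    }
    pmcid <- if (is.list(g$pmcid)) g$pmcid[[1]] else g$pmcid
    tt <- g$trait_tables
    if (is.list(tt)) tt <- unlist(tt)
    list(pmcid = pmcid,
         trait_tables = as.character(tt %||% character(0)),
         abbreviations = fix_df(g$abbreviations,
                                c("short_form", "long_form")),
         entities = fix_df(g$entities,
                           c("table_id", "row", "col", "term_id")),
         statements = fix_df(g$statements,
                             c("table_id", "row", "subject")))
  })
}
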