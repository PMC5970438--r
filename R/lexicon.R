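# Ontology dictionaries and concept matching via an embedded
# normalized longest-match term index.

dictionary_categories <- c("phenotypic", "genotypic", "chemical",
                           "marker", "statistical")

# Tie-break priority across dictionaries (trait identity first).
source_priority <- c(
  SPTO = 1, TO = 2, PO = 3, PATO = 4, ChEBI = 5, GO = 6, SO = 7,
  "SGN-markers" = 8, "SGN-genes" = 9, STATO = 10)

source_rank <- function(source) {
  r <- unname(source_priority[source])
  r[is.na(r)] <- 99
  r
}

new_entry <- function(term_id, label, synonyms, source, category) {
  list(term_id = term_id, label = label, synonyms = synonyms,
       source = source, category = category)
}

#' Load a dictionary from an OBO flat file
#'
#' Reads `[Term]` stanzas, keeping the `id` as the term CURIE, `name` as
#' the preferred label and every `synonym` line (all scopes) as a synonym;
#' obsolete terms are excluded.
#'
#' @param path OBO file path.
#' @param source Dictionary name (e.g. `"TO"`, `"ChEBI"`).
#' @param category Entry category, one of `"phenotypic"`, `"genotypic"`,
#'   `"chemical"`, `"marker"`, `"statistical"`.
#' @return List of dictionary entries (`term_id`, `label`, `synonyms`,
#'   `source`, `category`).
#' @export
load_obo <- function(path, source, category) {
  category <- match.arg(category, dictionary_categories)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  entries <- list()
  in_term <- FALSE
  cur <- NULL
  flush <- function(cur) {
    if (!is.null(cur) && !cur$obsolete && nzchar(cur$id) && nzchar(cur$name)) {
      entries[[length(entries) + 1L]] <<- new_entry(
        cur$id, cur$name, cur$synonyms, source, category)
    }
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "[Term]") {
      flush(cur)
      in_term <- TRUE
      cur <- list(id = "", name = "", synonyms = character(0),
                  obsolete = FALSE)
      next
    }
    if (grepl("^\\[", line)) {  # other stanza type
      flush(cur)
      in_term <- FALSE
      cur <- NULL
      next
    }
    if (!in_term || !nzchar(line)) next
    if (grepl("^id:", line)) {
      cur$id <- trimws(sub("^id:", "", line))
    } else if (grepl("^name:", line)) {
      cur$name <- trimws(sub("^name:", "", line))
    } else if (grepl("^synonym:", line)) {
      syn <- regmatches(line, regexpr('"[^"]*"', line))
      if (length(syn) == 1) {
        cur$synonyms <- c(cur$synonyms, substring(syn, 2, nchar(syn) - 1))
      } else {
        stop("unparseable synonym line ", i, " in ", path, call. = FALSE)
      }
    } else if (grepl("^is_obsolete:\\s*true", line)) {
      cur$obsolete <- TRUE
    }
  }
  flush(cur)
  entries
}

#' Load a dictionary from a flat TSV term list
#'
#' Expects tab-separated rows `term_id<TAB>label`, with any additional
#' columns treated as synonyms. Rows with an empty id are skipped with a
#' warning.
#'
#' @inheritParams load_obo
#' @param path TSV file path.
#' @return List of dictionary entries.
#' @export
load_tsv <- function(path, source, category) {
  category <- match.arg(category, dictionary_categories)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  entries <- list()
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (length(fields) < 2 || !nzchar(fields[1])) {
      warning("row ", i, " of ", path, " skipped (missing id or label)",
              call. = FALSE)
      next
    }
    syn <- if (length(fields) > 2) fields[-(1:2)] else character(0)
    syn <- syn[nzchar(syn)]
    entries[[length(entries) + 1L]] <- new_entry(
      fields[1], fields[2], syn, source, category)
  }
  entries
}

greek_map <- c(
  "α" = "alpha", "β" = "beta", "γ" = "gamma",
  "δ" = "delta", "ε" = "epsilon", "ζ" = "zeta",
  "η" = "eta", "θ" = "theta", "κ" = "kappa",
  "λ" = "lambda", "μ" = "mu", "π" = "pi",
  "ρ" = "rho", "σ" = "sigma", "τ" = "tau",
  "φ" = "phi", "χ" = "chi", "ψ" = "psi",
  "ω" = "omega")

#' Normalize a term for dictionary matching
#'
#' Applies Unicode compatibility normalization (NFKC), case-folding, a
#' fixed Greek-letter transliteration (so `β`-carotene and
#' beta-carotene unify), collapses internal whitespace and hyphens to
#' single spaces, and strips leading/trailing punctuation.
#'
#' @param text Character vector.
#' @return Normalized character vector.
#' @export
normalize_term <- function(text) {
  x <- stringi::stri_trans_nfkc(text)
  x <- tolower(x)
  for (g in names(greek_map)) {
    x <- gsub(g, greek_map[[g]], x, fixed = TRUE)
  }
  x <- gsub("[-[:space:]]+", " ", x)
  gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", x)
}

#' Build a term index from dictionary entries
#'
#' Keys the index by the normalized form of every label and synonym;
#' entries from different sources sharing a normalized key are all
#' retained under that key. The index replaces an external search server
#' with an equivalent embedded contract: exact normalized lookup,
#' leftmost-longest scanning.
#'
#' @param entries List of dictionary entries from [load_obo()] /
#'   [load_tsv()], possibly concatenated across sources.
#' @return A `term_index` object.
#' @export
build_index <- function(entries) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  max_tokens <- 0L
  for (e in entries) {
    for (txt in c(e$label, e$synonyms)) {
      key <- normalize_term(txt)
      if (!nzchar(key)) next
      ntok <- length(strsplit(key, " ", fixed = TRUE)[[1]])
      max_tokens <- max(max_tokens, ntok)
      bucket <- if (exists(key, envir = env, inherits = FALSE)) {
        get(key, envir = env, inherits = FALSE)
      } else {
        list()
      }
      bucket[[length(bucket) + 1L]] <- e
      assign(key, bucket, envir = env)
    }
  }
  structure(list(entries = env, max_term_tokens = max_tokens,
                 n_entries = length(entries)),
            class = "term_index")
}

#' @export
print.term_index <- function(x, ...) {
  cat("<term_index> ", x$n_entries, " entries, ",
      length(ls(x$entries)), " normalized keys, max term length ",
      x$max_term_tokens, " tokens\n", sep = "")
  invisible(x)
}

index_lookup <- function(index, key) {
  if (!nzchar(key)) return(NULL)
  if (exists(key, envir = index$entries, inherits = FALSE)) {
    get(key, envir = index$entries, inherits = FALSE)
  } else {
    NULL
  }
}

empty_matches <- function() {
  data.frame(term_id = character(0), label = character(0),
             category = character(0), source = character(0),
             start = integer(0), end = integer(0),
             matched_text = character(0), stringsAsFactors = FALSE)
}

#' Annotate text with dictionary concepts
#'
#' Greedy leftmost-longest token-window scan: at each token position,
#' windows from the index's longest term length down to one token are
#' tried; the window text is matched via [normalize_term()], and on a hit
#' the match is emitted and the scan resumes after it, so the returned
#' spans are sorted and non-overlapping. Ties across dictionaries resolve
#' by a fixed source priority (SPTO > TO > PO > PATO > ChEBI > GO > SO >
#' SGN-markers > SGN-genes > STATO).
#'
#' @param text A single string.
#' @param index A `term_index` from [build_index()].
#' @return Data frame of concept matches with columns `term_id`, `label`,
#'   `category`, `source`, `start`, `end` (0-based, half-open character
#'   offsets into `text`) and `matched_text`.
#' @export
annotate <- function(text, index) {
  stopifnot(inherits(index, "term_index"))
  if (is.na(text) || !nzchar(text) || index$max_term_tokens == 0L) {
    return(empty_matches())
  }
  toks <- gregexpr("[^[:space:]]+", text)[[1]]
  if (toks[1] == -1) return(empty_matches())
  tok_start <- as.integer(toks)
  tok_end <- tok_start + attr(toks, "match.length") - 1L
  n <- length(tok_start)
  rows <- list()
  i <- 1L
  while (i <= n) {
    hit <- NULL
    for (w in seq.int(min(index$max_term_tokens, n - i + 1L), 1L)) {
      j <- i + w - 1L
      s <- tok_start[i]
      e <- tok_end[j]
      frag <- substring(text, s, e)
      bucket <- index_lookup(index, normalize_term(frag))
      if (!is.null(bucket)) {
        ranks <- vapply(bucket, function(b) source_rank(b$source), numeric(1))
        best <- bucket[[which.min(ranks)]]
        hit <- data.frame(
          term_id = best$term_id, label = best$label,
          category = best$category, source = best$source,
          start = s - 1L, end = e, matched_text = frag,
          stringsAsFactors = FALSE)
        i <- j + 1L
        break
      }
    }
    if (is.null(hit)) {
      i <- i + 1L
    } else {
      rows[[length(rows) + 1L]] <- hit
    }
  }
  if (length(rows) == 0) return(empty_matches())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The bundled mini-dictionary
#'
#' Loads the small trait/chemical dictionary shipped with the package
#' (Solanaceae phenotype terms, trait-ontology terms and one ChEBI
#' compound), which is sufficient to exercise every annotation path
#' offline. Term identifiers are stored verbatim as printed in their
#' sources, including two entries (`SP:00000378`, `TO:000269`) whose
#' digit counts deviate from the usual CURIE width.
#'
#' @param extra_entries Optional list of additional entries (e.g. a
#'   synthetic marker list) appended before indexing.
#' @return List of dictionary entries; pass to [build_index()].
#' @export
mini_dictionary <- function(extra_entries = list()) {
  dir <- system.file("extdata", "dictionaries", package = "qtlminer")
  entries <- c(
    load_tsv(file.path(dir, "spto_mini.tsv"), "SPTO", "phenotypic"),
    load_tsv(file.path(dir, "to_mini.tsv"), "TO", "phenotypic"),
    load_tsv(file.path(dir, "chebi_mini.tsv"), "ChEBI", "chemical"))
  c(entries, extra_entries)
}

#' Load dictionaries declared in a configuration list
#'
#' Each declaration is a list with `source`, `path`, `format` (`"obo"` or
#' `"tsv"`) and `category`; see [load_obo()] and [load_tsv()].
#'
#' @param declarations List of dictionary declarations.
#' @return Concatenated list of dictionary entries.
#' @export
load_dictionaries <- function(declarations) {
  out <- list()
  for (d in declarations) {
    entries <- switch(
      match.arg(d$format, c("tsv", "obo")),
      tsv = load_tsv(d$path, d$source, d$category),
      obo = load_obo(d$path, d$source, d$category))
    out <- c(out, entries)
  }
  out
}
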