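---
title: "Mining QTL statements from article tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining QTL statements from article tables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlminer)
```

## The problem

Quantitative trait loci (QTL) — genomic regions statistically associated
with variation in a quantitative phenotype — are the central currency of
plant-breeding genetics, yet most published QTL results live in tables,
not prose. Text-mining methods built for running text miss them, and
tables in the wild are heterogeneous: horizontal or vertical layouts,
multi-row nested headers, cells spanning several rows or columns,
abbreviated trait names defined elsewhere in the article, and footnote
glyphs glued onto numbers. `qtlminer` turns such tables, as published in
JATS-compliant full-text XML, into machine-readable *QTL statements*:
one per table row, a trait-descriptor subject plus
(predicate = column heading, object = cell value) pairs, each optionally
annotated with an ontology concept.

The pipeline has six stages, each an exported function so every stage is
independently testable:

1. **Retrieval** (`fetch_fulltext`, `read_article`, `extract_tables`) —
   articles come from the Europe PMC `fullTextXML` endpoint (cached to
   disk, one file per PMCID) or from local files; tables are the
   `<table-wrap>` elements of the article body, matched by local name so
   namespace dialects do not matter. Inline markup is flattened to its
   text, deliberately keeping footnote glyphs (`**`, superscript
   letters) in the cell text. Supplementary files are not parsed.
2. **Normalization** (`normalize_table`) — span resolution, orientation
   detection, optional transposition, header merging, per-column
   datatype inference.
3. **Abbreviation expansion** (`collect_article_abbreviations`,
   `expand_table`) — the Schwartz–Hearst pairing of parenthesized short
   forms with adjacent long forms.
4. **Annotation** (`build_index`, `annotate`) — exact normalized
   longest-match lookup against ontology dictionaries.
5. **Classification and extraction** (`classify_columns`,
   `extract_statements`, `merge_statements`).
6. **Persistence** (`write_sqlite`, `write_statements_csv`,
   `export_rdf`).

## Normalization rules

**Span resolution.** Each cell with `rowspan` r and `colspan` c is
replicated into all r×c covered grid positions, cells occupying the
first free column of their row (the HTML placement rule). Two cells
claiming one position is an error, not a silent overwrite. Ragged rows
are padded with empty strings. The covered-position count equals
Σ(rowspan×colspan), a conservation law the test suite checks on hundreds
of randomized layouts.

**Orientation.** A table with an explicit header section is horizontal.
For headerless tables we treat the first column as a candidate label
column and compare datatype homogeneity of the remaining block: the mean
within-row purity (fraction of non-empty cells sharing the majority
datatype) against the mean within-column purity. Records running down
the columns make rows pure and columns mixed, so strictly greater row
homogeneity means vertical; ties — including all-numeric grids and
single-cell tables — go to horizontal, the common case. This heuristic
is our own design; the underlying problem (vertical layouts exist and
must be transposed before a header row can be named) admits many rules,
and we chose the simplest deterministic one. Orientation is resolved
*before* header merging, so a table cannot be both transposed and
nested-header-merged from the same axis; we have not seen a layout that
needs both, and the order is recorded with the table.

**Header merging.** After span resolution a multi-row header collapses
to one heading per column: distinct non-empty texts concatenated
top-to-bottom with single spaces, skipping consecutive duplicates (which
are exactly the artifacts of span replication). `["QTL","QTL"]` over
`["start","end"]` becomes `"QTL start"`, `"QTL end"`.

**Datatypes.** A column is `numeric` iff all its non-empty cells parse
as integers, decimals, signed or scientific-notation numbers (thousands
separators accepted) and at least one cell is non-empty — "exclusively
numerical" cannot be asserted of an empty column, so all-empty columns
are `alphanumeric`. Decimal commas are *not* accepted: without evidence
of locale-specific numbers in the source material we keep the parser
strict rather than guessing. The flag `strip_glyphs` controls whether
trailing footnote glyphs (`*`, `†`, `‡`, `§`, superscript letters) are
stripped before parsing. The default is **off**, which reproduces a
documented legacy failure mode — a numeric column carrying `**` marks is
read as alphanumeric, becomes eligible for text-column roles, and can
spawn spurious statements (see below). Production runs should pass
`strip_glyphs = TRUE`; the default stays legacy so the failure mechanism
remains demonstrable, and stripping is monotone (every column numeric
without stripping stays numeric with it).

## Abbreviation expansion

Definitions are recognized in the two parenthesized patterns
`long form (short form)` and `short form (long form)`. A candidate short
form must be 2–10 characters, contain a letter, and start with an
alphanumeric character; the long-form search window is limited to
min(|short|+5, 2·|short|) words. The matcher scans the window right to
left, placing each alphanumeric character of the short form at its
rightmost feasible position, with the first character anchored at a word
start; the result is the shortest suffix of the window containing the
short form's characters in order. The test suite proves this greedy scan
equivalent to brute-force suffix enumeration on over a thousand random
windows.

Because the method is purely rule-based it behaves in an all-or-nothing
way: definitions written in the supported patterns are recovered
completely, definitions in any other format (dashes, colons, footnote
prose) are recovered not at all. The synthetic generator has a
`malformed_abbrev` mode precisely to pin this property in tests.

Pairs are collected from every caption, footer and cell and — beyond the
tables themselves — from the article's body paragraphs, since articles
routinely define a trait's abbreviation at first mention in the text and
then use only the short form in tables. Each pair is tagged with its
source so the table-only behaviour can be recovered by filtering. When
one short form has competing definitions, the one found nearest the
table wins (cell > footer > caption > body paragraph). Expansion
replaces whole tokens only (boundaries are non-alphanumeric characters),
so marker identifiers such as `CT99` can never be corrupted, and numeric
columns are never touched.

## Concept annotation

Dictionaries load from OBO flat files or two-column TSV term lists into
a single in-memory index keyed by a normalized term form: Unicode
compatibility normalization, case folding, a fixed Greek-letter
transliteration (`β-carotene` and `beta carotene` unify), hyphens and
whitespace collapsed, edge punctuation stripped. Matching is exact on
the normalized form — no fuzzy or stemmed matching, trading recall for
the high precision appropriate to annotation that downstream users will
treat as ground truth. The scanner is greedy leftmost-longest over token
windows, so if both `fruit` and `fruit shape` are indexed, the text
"fruit shape" yields exactly one match (the longer), and returned spans
never overlap. Ties across dictionaries resolve by a fixed source
priority (SPTO > TO > PO > PATO > ChEBI > GO > SO > SGN-markers >
SGN-genes > STATO), putting trait identity first; the mapping from
source to category (phenotypic, genotypic, chemical, marker,
statistical) is likewise fixed.

The package bundles a mini-dictionary of trait, phenotype and compound
terms sufficient to exercise every annotation path offline. Two of its
identifiers (`SP:00000378`, `TO:000269`) have nonstandard digit counts;
they are stored verbatim as printed in their source rather than
"corrected", since guessing the intended identifier would be worse than
faithfully carrying the printed one.

## Column classification and statement extraction

Columns classify into three categories:

* **value** — numeric datatype (a statistical-ontology annotation of the
  heading is attempted);
* **descriptor** — alphanumeric, with a phenotypic-dictionary match in
  the heading or any cell, *or* a trait/phenotype/QTL keyword in the
  heading;
* **property** — other alphanumeric columns matching chemical, gene or
  marker dictionaries.

Anything else stays unclassified but still contributes predicate–object
pairs (without annotation): a published table's content should survive
into the output even when no dictionary recognises it. The keyword
filter that admits tables into the pipeline matches whole words
case-insensitively against the table subject (caption + headings +
footer), tolerating a plural suffix so "QTLs" and "traits" count. The
default keyword set — trait, QTL, phenotype, phenotypic, quantitative
trait locus/loci — is configurable; it is a design choice, not a
discovered constant.

When several descriptor columns qualify, the leftmost wins —
deterministic, and matching the dominant layout in which the trait names
the row from the first column. One statement is emitted per body row
with a non-empty descriptor cell; rows listing several traits in one
cell are not split, because splitting rules would be guesswork. A
statement is emitted whenever a descriptor exists, even if no genotypic
column accompanies it; pair categories are recorded so stricter
definitions (e.g. requiring a marker) can be applied post hoc.

The `**` failure mode is now easy to state precisely: with stripping
off, a numeric column whose heading carries a filter keyword (say "QTL
effect") and whose cells carry `**` marks is read as alphanumeric, the
keyword rule promotes it to descriptor, and every row yields a spurious
statement whose "subject" is a starred number. With stripping on, the
column is numeric, classified value, and those statements vanish.

Statement groups (`merge_statements`) are keyed by the subject's concept
identifier when annotated, else by its normalized text — which is how
"AsA" in one table and "ascorbic acid" in another end up in the same
group once expansion and annotation have run.

## Outputs

The relational store is an SQLite database with six tables — `ARTICLE`,
`TRAIT_TABLE`, `ABBREVIATION`, `QTL`, `COLUMN_ENTRY`, `CELL_ENTRY` —
with foreign keys from `TRAIT_TABLE` to `ARTICLE` and from the
column/cell/QTL tables to `TRAIT_TABLE`. The column layouts are this
package's own minimal design (identifiers, foreign keys, text fields,
coordinates). One `QTL` row is written per statement; pairs are
reconstructable by joining with `CELL_ENTRY` and `COLUMN_ENTRY`, and the
CSV (one row per pair, RFC 4180 quoting) carries the same logical
content. The RDF export writes N-Triples: one resource per statement row
(`<base>/article/<pmcid>/table/<id>/row/<n>`), one triple per pair with
the predicate minted from the slugged heading, annotated terms as
identifiers.org URIs, and a typing triple for annotated subjects — so
the triple count is exactly the pair count plus the number of annotated
subjects, an identity the tests assert on every corpus.

## The synthetic corpus generator

Real benchmark corpora for this task require downloading dozens of
articles and full ontology releases, so the package carries its own
generator (`generate_corpus`) producing JATS XML articles with known
gold annotations: trait tables drawing subjects from the bundled
mini-dictionary, marker columns backed by a generated synthetic marker
dictionary, LOD and chromosome value columns, and non-trait filler
tables (primer lists, field metadata) containing no filter keywords.
Structural variety is toggled per `corpus_spec` probability: vertical
orientation, nested two-row headers with spans, abbreviated trait names
with in-article definitions, footnote glyphs.

The reference conditions — the `corpus_spec()` defaults, chosen once —
are 10 articles, 2–3 tables each, trait-table fraction 0.6, vertical
probability 0.3, nested-header probability 0.3, abbreviation probability
0.5, glyphs off. These exercise every structure the pipeline fully
supports, so end-to-end precision and recall must be exactly 100% at all
four evaluation levels when the implementation is correct — the
acceptance suite asserts precisely that, and any deviation is a bug, not
noise. Generation is deterministic given the seed, to the byte.

What the generator does *not* emulate — and what perfect scores on it
therefore do not show about real articles: free-text caption variety
beyond the planted templates, definition formats outside the two
supported patterns, dictionary near-misses (synonym gaps, spelling
variants), tables whose subject lacks every filter keyword, multi-trait
cells, and OCR-era artifacts. On real corpora those are exactly the
sources of the false negatives and positives that keep recall below
100%; the published-count arithmetic in the acceptance script records
the scale of that gap on real data.

## Evaluation harness

Predictions are scored against gold at four levels, each with its own
matching key: trait table (article, table id), abbreviation (article,
short form, normalized long form), entity (article, table, cell
coordinates, term id), statement (article, table, row, normalized
subject) — statement matching is deliberately at row/subject
granularity, not pair-by-pair. Precision is 100·TP/(TP+FP), recall
100·TP/(TP+FN), displayed rounded half-up (not banker's) to two
decimals; an undefined denominator yields an explicit `NA`, never 0
or 100.

## Numerical choices and degenerate inputs

* Rounding: half away from zero at two decimals, implemented directly
  (`floor(x·100 + 0.5)/100`) since base `round()` rounds half to even.
* Single-cell and empty tables: horizontal, no statements, no errors.
* Zero-row headers yield empty headings; an empty caption or footer is
  an empty string, never absent.
* Duplicate abbreviation pairs dedupe case-sensitively; conflicting
  long forms resolve by source precedence, then first-found.
* Index keys that normalize to the empty string are dropped.
* RNG state is saved and restored around corpus generation, so calling
  the generator does not perturb a caller's random stream.

## Problem sizes in the test suite

The suite runs entirely offline in well under a minute: the randomized
normalization properties use 500 layouts up to 6×6, the matcher/oracle
equivalence 1000+ windows of at most 12 words, and the end-to-end
acceptance corpus the 10-article reference conditions above. These sizes
were chosen as the smallest at which the properties are convincing;
all of them scale up linearly if a maintainer wants heavier runs.

## Known limitations

* Only `<table-wrap>` elements in the article body are parsed;
  supplementary spreadsheets — where many QTL tables actually live —
  are out of scope.
* Exact-match annotation misses synonym and spelling variants absent
  from the loaded dictionaries.
* The orientation heuristic can misread a headerless table whose first
  column is data that happens to be textually mixed.
* Abbreviation recall is bounded by the two supported definition
  patterns.
* Cross-article abbreviation sharing and genome-coordinate resolution of
  QTL intervals are deliberately not attempted.
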