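# qtlminer

Semantic mining of quantitative trait locus (QTL) tables in full-text
scientific articles.

## What it does, and for whom

QTL mapping results — which genomic regions move which phenotypic
traits, with what LOD support and through which markers — are published
almost exclusively in article *tables*, in layouts too heterogeneous for
conventional text mining: vertical as well as horizontal orientations,
nested multi-row headers, row/column spans, abbreviated trait names, and
footnote glyphs stuck to numbers. `qtlminer` is for plant-breeding
researchers and database curators who need that information as data
rather than typography.

The package takes articles in JATS-compliant XML (fetched live from the
Europe PMC REST API by PMCID, with on-disk caching, or read from local
files) and runs a six-stage pipeline:

1. extract every `<table-wrap>` into a raw grid with span attributes;
2. normalize: resolve spans into a rectangular grid, detect and undo
   vertical orientation, merge nested headers into a single heading row,
   infer per-column datatypes;
3. find abbreviation definitions with the Schwartz–Hearst algorithm
   (`long form (short form)` and the reverse) and expand them in
   headings and cells;
4. annotate headings and cells against ontology dictionaries (trait,
   phenotype, chemical, marker, statistical term lists in OBO or TSV
   form) via an embedded exact-match, leftmost-longest term index;
5. filter trait tables by keyword, classify columns into trait
   **descriptors**, **properties** and **values**, and emit one *QTL
   statement* per row: a subject (the trait descriptor) plus
   (predicate = column heading, object = cell value) pairs;
6. persist to a six-table SQLite schema, a CSV (one row per
   predicate–object pair) and RDF N-Triples with identifiers.org term
   URIs.

Statements about the same trait merge across tables by ontology concept
(or normalized text), so "AsA" in Table 1 and "ascorbic acid" in Table 3
land in one group. The measures of merit are precision `TP/(TP+FP)` and
recall `TP/(TP+FN)` at four levels — trait table, abbreviation,
biological entity, QTL statement — computed by the built-in evaluation
harness against gold annotations.

A synthetic-corpus generator (`generate_corpus`) produces deterministic
JATS articles with known gold annotations covering every structural
feature above, so the whole pipeline is testable offline.

## Worked example

```r
library(qtlminer)

doc <- read_article(xml)   # a JATS article: one trait table, and a body
                           # paragraph "Total ascorbic acid (AsA) content
                           # was measured in ripe fruit."
markers <- list(
  list(term_id = "SGN-M123", label = "TG123", synonyms = character(0),
       source = "SGN-markers", category = "marker"),
  list(term_id = "SGN-M99",  label = "CT99",  synonyms = character(0),
       source = "SGN-markers", category = "marker"))
res <- mine_corpus(list(doc), mini_dictionary(markers))
res
#> <mining_result>
#>   articles:      1
#>   trait tables:  1
#>   abbreviations: 1
#>   statements:    2
#>   cell concepts: 4
res$statements[[1]]
#> <qtl_statement> PMC1234567/Tab1 row 0
#>   subject: ascorbic acid [CHEBI:22652]
#>   - Marker = TG123 [SGN-M123]
#>   - LOD = 3.5
```

The table's first row said `AsA | TG123 | 3.5`: the abbreviation found
in the body paragraph was expanded, the expanded subject annotated with
its ChEBI identifier, the marker with its (here synthetic) SGN
identifier, and the numeric LOD column became a value pair. Writing the
result out:

```r
write_sqlite(res, "results.sqlite")        # six-table relational schema
write_statements_csv(res$statements, "results.csv")
export_rdf(res$statements, "results.nt")   # pairs + typed subjects
```

A full synthetic round trip, from a shell:

```sh
qtlminer synth --out-dir corpus --seed 5
qtlminer mine  --input-dir corpus --sqlite r.sqlite --csv r.csv --rdf r.nt
qtlminer eval  --config eval.yaml
#> level        tp  fp  fn  precision  recall
#> trait_table  14   0   0        100     100
#> abbreviation 10   0   0        100     100
#> entity       86   0   0        100     100
#> statement    43   0   0        100     100
```

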