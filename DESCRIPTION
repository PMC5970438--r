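Package: qtlminer
Title: Semantic Mining of QTL Tables in Full-Text Scientific Articles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts quantitative trait locus (QTL) information buried in
    heterogeneous tables of full-text plant-science articles. Articles in
    JATS-compliant XML (fetched from the Europe PMC REST API or read from
    local files) are scanned for table-wrap elements; tables are normalized
    (row/column spans resolved, orientation detected, nested headers merged
    into a single heading row, per-column datatypes inferred), abbreviations
    are expanded with the Schwartz-Hearst algorithm, and cells are
    semantically annotated against ontology dictionaries (trait, phenotype,
    chemical, marker and statistical term lists) via an embedded
    longest-match term index. Columns are classified into trait descriptors,
    properties and values, and per-row QTL statements are emitted to a
    relational (SQLite) store, CSV and RDF N-Triples. A synthetic JATS
    corpus generator with gold annotations and a four-level precision/recall
    evaluation harness make the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    jsonlite,
    stats,
    stringi,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
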