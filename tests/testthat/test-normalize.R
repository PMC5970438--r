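test_that("span resolution replicates cells over their covered positions", {
  # identity when all spans are 1
  g <- resolve_spans(rows_of(c("A", "B")), rows_of(c("1", "2"), c("3", "4")))
  expect_equal(g$header, matrix(c("A", "B"), 1, byrow = TRUE))
  expect_equal(g$body, matrix(c("1", "2", "3", "4"), 2, byrow = TRUE))
  expect_equal(g$covered, 6)

  # colspan replication across a header row
  g <- resolve_spans(list(list(cellspec("Position", colspan = 2))),
                     rows_of(c("1", "2")))
  expect_equal(g$header[1, ], c("Position", "Position"))

  # rowspan replication down the first column
  g <- resolve_spans(list(), list(
    list(cellspec("fruit shape", rowspan = 2), cellspec("3.1")),
    list(cellspec("4.2"))))
  expect_equal(g$body[, 1], c("fruit shape", "fruit shape"))
  expect_equal(g$body[, 2], c("3.1", "4.2"))
})

test_that("overlapping spans raise a normalization error naming the position", {
  rows <- list(
    list(cellspec("a"), cellspec("b", rowspan = 2)),
    list(cellspec("c", colspan = 2)))
  expect_error(resolve_spans(list(), rows), "row 2")
})

test_that("ragged rows are padded with empty strings", {
  g <- resolve_spans(list(), rows_of(c("a", "b", "c"), c("d")))
  expect_equal(dim(g$body), c(2L, 3L))
  expect_equal(g$body[2, ], c("d", "", ""))
})

test_that("multi-row headers merge into one heading per column", {
  h <- matrix(c("Chr", "", "", "Position"), nrow = 2, byrow = TRUE)
  expect_equal(merge_header_rows(h), c("Chr", "Position"))

  h <- matrix(c("QTL", "QTL", "start", "end"), nrow = 2, byrow = TRUE)
  expect_equal(merge_header_rows(h), c("QTL start", "QTL end"))

  h <- matrix(c("Trait", "LOD"), nrow = 1)
  expect_equal(merge_header_rows(h), c("Trait", "LOD"))

  expect_equal(merge_header_rows(matrix(character(0), 0, 0), n_cols = 2),
               c("", ""))
})

test_that("orientation detection favours explicit headers and row homogeneity", {
  hdr <- matrix(c("Trait", "LOD"), 1)
  body <- matrix(c("fruit", "3.2"), 1)
  expect_equal(detect_orientation(hdr, body), "horizontal")

  # headerless grid with labels down the first column: per-row homogeneity
  # of the remaining 2x3 block is 1, per-column homogeneity 2/3
  no_hdr <- matrix(character(0), 0, 0)
  vert <- matrix(c("Trait", "fruit shape", "fruit weight",
                   "LOD", "3.5", "4.2",
                   "Chr", "2", "7"), nrow = 3, byrow = TRUE)
  expect_equal(detect_orientation(no_hdr, vert), "vertical")

  # all-numeric headerless grid: tie goes to horizontal
  nums <- matrix(c("1", "2", "3", "4"), 2, byrow = TRUE)
  expect_equal(detect_orientation(no_hdr, nums), "horizontal")

  # single-cell table defaults to horizontal
  expect_equal(detect_orientation(no_hdr, matrix("x", 1, 1)), "horizontal")
})

test_that("transposition is an involution that swaps indices", {
  g <- matrix(as.character(1:6), nrow = 2, byrow = TRUE)
  tg <- transpose_grid(g)
  expect_equal(dim(tg), c(3L, 2L))
  expect_equal(tg[2, 1], g[1, 2])
  expect_equal(transpose_grid(tg), g)
  expect_equal(transpose_grid(matrix("x", 1, 1)), matrix("x", 1, 1))
})

test_that("datatype inference is strict, glyph-aware and monotone", {
  expect_equal(infer_datatype(c("3.2", "4.5", "7.1")), "numeric")
  expect_equal(infer_datatype(c("12.3**", "4.5")), "alphanumeric")
  expect_equal(infer_datatype(c("12.3**", "4.5"), strip_glyphs = TRUE),
               "numeric")
  expect_equal(infer_datatype(c("TG123", "CT99")), "alphanumeric")
  expect_equal(infer_datatype(c("", "")), "alphanumeric")
  expect_equal(infer_datatype(c("1,234", "5,678.9")), "numeric")
  expect_equal(infer_datatype(c("3,2")), "alphanumeric")  # no decimal comma
  expect_equal(infer_datatype(c("-1.5e-3", "+2E4")), "numeric")
  expect_equal(infer_datatype(c("3.5", "")), "numeric")

  # monotonicity: numeric without stripping implies numeric with stripping
  set.seed(1)
  for (i in 1:50) {
    cells <- replicate(5, paste0(
      sample(c("12", "3.5", "x7", "9**", "1e3", ""), 1)))
    if (infer_datatype(cells) == "numeric") {
      expect_equal(infer_datatype(cells, strip_glyphs = TRUE), "numeric")
    }
  }
})

test_that("normalize_table composes the steps and is idempotent on its output", {
  raw <- make_raw_table(
    header_rows = list(
      list(cellspec("Trait", rowspan = 2), cellspec("QTL", colspan = 2)),
      rows_of(c("LOD", "Chr"))[[1]]),
    body_rows = rows_of(c("fruit shape", "3.5", "2"),
                        c("stem", "4.1", "7")),
    caption = "QTLs detected")
  nt <- normalize_table(raw)
  expect_equal(nt$headers$raw_heading, c("Trait", "QTL LOD", "QTL Chr"))
  expect_equal(nt$headers$datatype, c("alphanumeric", "numeric", "numeric"))
  expect_equal(nt$orientation, "horizontal")

  # vertical fixture: headers recovered from the first column
  vraw <- make_raw_table(
    body_rows = rows_of(c("Trait", "fruit shape", "stem"),
                        c("Marker", "TG1", "TG2"),
                        c("LOD", "3.5", "4.1")))
  vnt <- normalize_table(vraw)
  expect_equal(vnt$orientation, "vertical-transposed")
  expect_equal(vnt$headers$raw_heading, c("Trait", "Marker", "LOD"))
  expect_equal(vnt$body[, 1], c("fruit shape", "stem"))

  # re-normalizing the produced grids changes nothing
  for (t in list(nt, vnt)) {
    again <- normalize_table(make_raw_table(
      header_rows = rows_of(t$headers$raw_heading),
      body_rows = lapply(seq_len(nrow(t$body)),
                         function(i) lapply(t$body[i, ], cellspec))))
    expect_equal(again$headers$raw_heading, t$headers$raw_heading)
    expect_equal(again$headers$datatype, t$headers$datatype)
    expect_equal(unname(again$body), unname(t$body))
  }
})
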