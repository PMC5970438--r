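# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Escape a literal string for use inside a PCRE pattern.
regex_quote <- function(x) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
}

# TRUE for characters that count as word characters across scripts
# (Latin, Greek, digits); used for token boundaries and short-form checks.
is_word_char <- function(ch) {
  grepl("^[\\p{L}\\p{N}]$", ch, perl = TRUE)
}

# Round half away from zero to `digits` decimals (base round() is banker's).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Whole-word (token-boundary) regex for a literal string; boundaries are
# non-letter, non-digit characters so marker IDs like "CT99" stay intact.
word_pattern <- function(x) {
  paste0("(?<![\\p{L}\\p{N}])", regex_quote(x), "(?![\\p{L}\\p{N}])")
}
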