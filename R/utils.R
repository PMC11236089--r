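#' @importFrom rlang abort warn inform %||%
#' @importFrom stats median rnbinom runif sd setNames
#' @importFrom utils head
NULL

# Classed conditions; the CLI maps classes to exit codes.
abort_lookup <- function(msg, ...) {
  abort(msg, class = "spottype_lookup_error", ...)
}

abort_validation <- function(msg, ...) {
  abort(msg, class = "spottype_validation_error", ...)
}

abort_format <- function(msg, ...) {
  abort(msg, class = "spottype_format_error", ...)
}

abort_no_overlap <- function(msg, ...) {
  abort(msg, class = "spottype_no_marker_overlap", ...)
}

#' Canonicalize gene symbols
#'
#' Trims whitespace, drops empty strings, uppercases, and deduplicates while
#' preserving first-seen order. All gene symbols in the package are stored in
#' this single canonical case.
#'
#' @param x character vector of gene symbols.
#' @return character vector of canonical symbols.
#' @keywords internal
canonicalize_genes <- function(x) {
  x <- trimws(as.character(x))
  x <- x[!is.na(x) & nzchar(x)]
  unique(toupper(x))
}

# Split a comma-separated gene field into a canonical symbol vector.
split_gene_field <- function(field) {
  if (is.na(field) || !nzchar(trimws(field))) return(character(0))
  canonicalize_genes(strsplit(field, ",", fixed = TRUE)[[1]])
}

# Deterministic substream seeds: stages of a pipeline draw from independent
# streams derived from one master seed, all below 2^31.
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483647)
}

# Lexicographic argmax: index of the maximum, ties broken by the
# lexicographically smallest label. `labels` must align with `x`.
argmax_lex <- function(x, labels) {
  top <- max(x)
  cand <- which(x == top)
  cand[order(labels[cand])][1]
}
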