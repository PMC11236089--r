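#' Genes-by-spots expression matrix
#'
#' Light container for spatial expression data: a numeric (possibly sparse)
#' matrix with genes as rows and spots as columns, plus a `layer` tag saying
#' what the values are. Gene symbols are canonicalized (uppercased) on
#' construction; duplicate gene or spot identifiers are rejected.
#'
#' @param values numeric matrix or `Matrix` sparse matrix, genes x spots,
#'   with rownames (gene symbols) and colnames (spot barcodes).
#' @param layer one of `"counts"` (non-negative raw counts), `"normalized"`
#'   (library-size or otherwise normalized, non-negative not required) or
#'   `"zscored"` (each row centred and scaled across spots).
#' @return a `spot_matrix` object.
#' @examples
#' m <- matrix(rpois(6, 2), nrow = 3,
#'             dimnames = list(c("G1", "G2", "G3"), c("s1", "s2")))
#' spot_matrix(m, "counts")
#' @export
spot_matrix <- function(values, layer = c("counts", "normalized", "zscored")) {
  layer <- match.arg(layer)
  if (is.null(rownames(values)) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    abort_validation("spot_matrix values need gene rownames and spot colnames")
  }
  rownames(values) <- toupper(trimws(rownames(values)))
  if (anyDuplicated(rownames(values))) {
    abort_validation("duplicate gene identifiers in spot_matrix")
  }
  if (anyDuplicated(colnames(values))) {
    abort_validation("duplicate spot identifiers in spot_matrix")
  }
  if (layer == "counts" && length(values) > 0 && min(values) < 0) {
    abort_validation("layer 'counts' requires non-negative values")
  }
  if (layer == "zscored" && ncol(values) > 1 && nrow(values) > 0) {
    dense <- as.matrix(values)
    mu <- rowMeans(dense)
    s <- apply(dense, 1, sd)
    ok <- is.finite(mu) & is.finite(s) & abs(mu) <= 1e-8 & abs(s - 1) <= 1e-8
    if (!all(ok)) {
      abort_validation("layer 'zscored' requires per-gene mean 0 and sd 1 (tol 1e-8)")
    }
  }
  structure(list(values = values, layer = layer), class = "spot_matrix")
}

#' @export
print.spot_matrix <- function(x, ...) {
  cat(sprintf("<spot_matrix> %d genes x %d spots, layer = %s\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' @export
dim.spot_matrix <- function(x) dim(x$values)

#' Gene and spot identifiers of a spot matrix
#' @param x a [spot_matrix()].
#' @return character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
spot_ids <- function(x) colnames(x$values)
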