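#' Read a Matrix Market expression bundle
#'
#' Reads the three-file bundle used by most spot-based pipelines:
#' `matrix.mtx` (genes as rows), `features.tsv` (gene id and gene symbol
#' columns, no header) and `barcodes.tsv` (one barcode per line). Each file
#' may be gzipped (`.gz`). Gene symbols are canonicalized; features sharing a
#' symbol are collapsed by summing their rows, with a warning.
#'
#' @param dir directory containing the bundle.
#' @return a [spot_matrix()] with layer `counts`.
#' @export
read_mtx_bundle <- function(dir) {
  mtx <- bundle_file(dir, "matrix.mtx")
  feat <- bundle_file(dir, "features.tsv")
  bc <- bundle_file(dir, "barcodes.tsv")
  m <- Matrix::readMM(mtx)
  features <- readr::read_tsv(feat, col_names = FALSE,
                              col_types = readr::cols(.default = readr::col_character()),
                              progress = FALSE)
  barcodes <- readr::read_tsv(bc, col_names = FALSE,
                              col_types = readr::cols(.default = readr::col_character()),
                              progress = FALSE)
  if (nrow(features) != nrow(m)) {
    abort_format(sprintf("matrix.mtx has %d rows but features.tsv has %d lines",
                         nrow(m), nrow(features)))
  }
  if (nrow(barcodes) != ncol(m)) {
    abort_format(sprintf("matrix.mtx has %d columns but barcodes.tsv has %d lines",
                         ncol(m), nrow(barcodes)))
  }
  symbol_col <- if (ncol(features) >= 2) 2 else 1
  symbols <- toupper(trimws(features[[symbol_col]]))
  if (anyDuplicated(symbols)) {
    warn(sprintf("%d duplicated gene symbol(s) in features.tsv; summing their rows",
                 sum(duplicated(symbols))))
    groups <- unique(symbols)
    agg <- Matrix::sparseMatrix(
      i = match(symbols, groups), j = seq_along(symbols), x = 1,
      dims = c(length(groups), length(symbols))
    )
    m <- agg %*% m
    symbols <- groups
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(symbols, barcodes[[1]])
  spot_matrix(m, layer = "counts")
}

bundle_file <- function(dir, base) {
  for (cand in c(file.path(dir, base), file.path(dir, paste0(base, ".gz")))) {
    if (file.exists(cand)) return(cand)
  }
  abort_format(sprintf("no %s[.gz] found in %s", base, dir))
}

#' Write a Matrix Market expression bundle
#'
#' Inverse of [read_mtx_bundle()]: writes `matrix.mtx`, `features.tsv`
#' (gene symbol duplicated as id and symbol) and `barcodes.tsv`.
#'
#' @param expr a [spot_matrix()] with layer `counts`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_mtx_bundle <- function(expr, dir) {
  stopifnot(inherits(expr, "spot_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(expr$values, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  readr::write_tsv(
    tibble::tibble(id = gene_ids(expr), symbol = gene_ids(expr)),
    file.path(dir, "features.tsv"), col_names = FALSE, progress = FALSE
  )
  readr::write_tsv(
    tibble::tibble(barcode = spot_ids(expr)),
    file.path(dir, "barcodes.tsv"), col_names = FALSE, progress = FALSE
  )
  invisible(dir)
}

#' Read spot geometry from a tissue positions CSV
#'
#' Parses the position file dialects used by spot-based platforms: six
#' columns `barcode`, `in_tissue`, `array_row`, `array_col`,
#' `pxl_row_in_fullres`, `pxl_col_in_fullres`, with or without a header
#' line (detected from the first field). Micron coordinates are derived from
#' full-resolution pixel coordinates via `um_per_px`, using the image
#' convention: origin top-left, x = column, y = row increasing downward,
#' 0-based.
#'
#' `in_tissue = 0` rows are retained but flagged; filtering is the caller's
#' choice.
#'
#' @param path CSV path.
#' @param diameter_um capture-spot diameter in microns.
#' @param um_per_px microns per full-resolution pixel; default 1.
#' @return a `spot_geometry` tibble with columns `barcode`, `in_tissue`,
#'   `array_row`, `array_col`, `x_um`, `y_um`; attribute `spot_diameter_um`.
#' @export
read_tissue_positions <- function(path, diameter_um, um_per_px = 1) {
  if (diameter_um <= 0) abort_validation("diameter_um must be > 0")
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  cols <- c("barcode", "in_tissue", "array_row", "array_col",
            "pxl_row_in_fullres", "pxl_col_in_fullres")
  tbl <- readr::read_csv(
    path, col_names = if (has_header) TRUE else cols,
    col_types = readr::cols(
      barcode = readr::col_character(), .default = readr::col_double()
    ),
    progress = FALSE
  )
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0) {
    abort_format(sprintf("tissue positions file is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  spot_geometry(
    barcode = tbl$barcode,
    in_tissue = as.integer(tbl$in_tissue) == 1L,
    array_row = as.integer(tbl$array_row),
    array_col = as.integer(tbl$array_col),
    x_um = tbl$pxl_col_in_fullres * um_per_px,
    y_um = tbl$pxl_row_in_fullres * um_per_px,
    spot_diameter_um = diameter_um
  )
}

#' Construct spot geometry
#'
#' @param barcode unique spot barcodes.
#' @param in_tissue logical flag per spot.
#' @param array_row,array_col integer lattice indices.
#' @param x_um,y_um finite micron coordinates (image convention: origin
#'   top-left, y increasing downward).
#' @param spot_diameter_um capture diameter in microns, > 0.
#' @return a `spot_geometry` tibble.
#' @export
spot_geometry <- function(barcode, in_tissue, array_row, array_col,
                          x_um, y_um, spot_diameter_um) {
  if (anyDuplicated(barcode)) abort_validation("spot barcodes must be unique")
  if (spot_diameter_um <= 0) abort_validation("spot_diameter_um must be > 0")
  if (any(!is.finite(x_um)) || any(!is.finite(y_um))) {
    abort_validation("spot coordinates must be finite")
  }
  out <- tibble::tibble(
    barcode = as.character(barcode), in_tissue = as.logical(in_tissue),
    array_row = as.integer(array_row), array_col = as.integer(array_col),
    x_um = as.numeric(x_um), y_um = as.numeric(y_um)
  )
  attr(out, "spot_diameter_um") <- spot_diameter_um
  class(out) <- c("spot_geometry", class(out))
  out
}

#' Write spot geometry as a headered tissue positions CSV
#' @param geom a `spot_geometry`.
#' @param path output CSV path.
#' @param um_per_px microns per pixel used to convert back; default 1.
#' @return `path`, invisibly.
#' @export
write_tissue_positions <- function(geom, path, um_per_px = 1) {
  out <- tibble::tibble(
    barcode = geom$barcode,
    in_tissue = as.integer(geom$in_tissue),
    array_row = geom$array_row,
    array_col = geom$array_col,
    pxl_row_in_fullres = geom$y_um / um_per_px,
    pxl_col_in_fullres = geom$x_um / um_per_px
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write annotation results as TSV
#'
#' Columns: `spot_id` (plus `cluster_id` in cluster mode), `assigned_label`,
#' `top_score`, `runner_up`, `margin`, in input spot order.
#'
#' @param result a `spot_annotation` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(result, path) {
  readr::write_tsv(as.data.frame(result), path, na = "", progress = FALSE)
  invisible(path)
}

#' Read annotation results written by [write_annotations()]
#' @param path TSV path.
#' @return a `spot_annotation` tibble.
#' @export
read_annotations <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      spot_id = readr::col_character(),
      assigned_label = readr::col_character(),
      runner_up = readr::col_character(),
      .default = readr::col_double()
    ),
    na = "", progress = FALSE
  )
  if ("cluster_id" %in% names(tbl)) tbl$cluster_id <- as.character(tbl$cluster_id)
  annotation_result(tbl, mode = if ("cluster_id" %in% names(tbl)) "cluster" else "spot")
}
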