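#' Construct a marker database
#'
#' A marker database holds, for each (tissue, cell type) pair, a set of
#' positive marker genes (characteristically high in that cell type) and an
#' optional set of negative markers (characteristically low). It is the core
#' reference object of marker-based annotation: no single-cell atlas is
#' needed, only these curated gene sets.
#'
#' Invariants enforced here: (tissue, cell type) pairs are unique; positive
#' and negative sets of one entry are disjoint; every entry has at least one
#' positive gene; symbols are canonicalized (trimmed, uppercased,
#' deduplicated).
#'
#' @param tissue character vector of tissue labels, one per entry.
#' @param cell_type character vector of cell-type labels, one per entry.
#' @param positive_genes list of character vectors of positive marker symbols.
#' @param negative_genes list of character vectors of negative marker symbols;
#'   defaults to empty sets.
#' @return a `marker_db` tibble with columns `tissue`, `cell_type`,
#'   `positive_genes` (list), `negative_genes` (list).
#' @examples
#' db <- marker_db(
#'   tissue = c("Brain", "Brain"),
#'   cell_type = c("Astrocyte", "Neuron"),
#'   positive_genes = list(c("GFAP", "AQP4"), c("RBFOX3", "SYT1")),
#'   negative_genes = list(character(0), "GFAP")
#' )
#' db
#' @export
marker_db <- function(tissue, cell_type, positive_genes,
                      negative_genes = rep(list(character(0)), length(tissue))) {
  if (!is.list(positive_genes)) positive_genes <- list(positive_genes)
  if (!is.list(negative_genes)) negative_genes <- list(negative_genes)
  tbl <- tibble::tibble(
    tissue = as.character(tissue),
    cell_type = as.character(cell_type),
    positive_genes = unname(purrr::map(positive_genes, canonicalize_genes)),
    negative_genes = unname(purrr::map(negative_genes, canonicalize_genes))
  )
  validate_marker_db(tbl)
}

validate_marker_db <- function(tbl) {
  key <- paste(tbl$tissue, tbl$cell_type, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tbl[duplicated(key), , drop = FALSE]
    abort_validation(sprintf(
      "duplicate (tissue, cell type) entry: (%s, %s)",
      dup$tissue[1], dup$cell_type[1]
    ))
  }
  for (i in seq_len(nrow(tbl))) {
    both <- intersect(tbl$positive_genes[[i]], tbl$negative_genes[[i]])
    if (length(both) > 0) {
      abort_validation(sprintf(
        "gene %s is listed as both positive and negative marker for (%s, %s)",
        both[1], tbl$tissue[i], tbl$cell_type[i]
      ))
    }
    if (length(tbl$positive_genes[[i]]) == 0) {
      abort_validation(sprintf(
        "entry (%s, %s) has no positive marker genes",
        tbl$tissue[i], tbl$cell_type[i]
      ))
    }
  }
  class(tbl) <- c("marker_db", class(tbl))
  tbl
}

#' Read a marker database from a TSV file
#'
#' The file dialect follows the public cell-type marker database layout:
#' a UTF-8 TSV with header columns `tissueType`, `cellName`,
#' `geneSymbolmore1` (comma-separated positive markers) and `geneSymbolmore2`
#' (comma-separated negative markers, possibly empty). Users may supply their
#' own marker panels in the same format, e.g. for less-studied organisms or
#' specialized tissues.
#'
#' @param path path to the TSV file.
#' @param tissue_filter optional tissue label; when given, only entries of
#'   that tissue are returned.
#' @return a validated [marker_db()] tibble.
#' @export
load_marker_db <- function(path, tissue_filter = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("tissueType", "cellName", "geneSymbolmore1", "geneSymbolmore2")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort_format(sprintf("marker database file is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (!is.null(tissue_filter)) {
    tbl <- tbl[trimws(tbl$tissueType) == tissue_filter, , drop = FALSE]
  }
  marker_db(
    tissue = trimws(tbl$tissueType),
    cell_type = trimws(tbl$cellName),
    positive_genes = purrr::map(tbl$geneSymbolmore1, split_gene_field),
    negative_genes = purrr::map(tbl$geneSymbolmore2, split_gene_field)
  )
}

#' Write a marker database to a TSV file
#'
#' Inverse of [load_marker_db()]; genes are joined with commas.
#'
#' @param db a `marker_db`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_db <- function(db, path) {
  out <- tibble::tibble(
    tissueType = db$tissue,
    cellName = db$cell_type,
    geneSymbolmore1 = purrr::map_chr(db$positive_genes, paste, collapse = ","),
    geneSymbolmore2 = purrr::map_chr(db$negative_genes, paste, collapse = ",")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

db_tissue_entries <- function(db, tissue) {
  sub <- db[db$tissue == tissue, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort_lookup(sprintf("tissue '%s' not found in marker database", tissue))
  }
  sub
}

#' Gene specificity weights for a tissue's marker panel
#'
#' A gene that marks a single cell type carries more information than one
#' shared by many; the score therefore up-weights specific markers. With `N`
#' cell types in the tissue and `n_g` of them listing gene `g` among their
#' positive or negative markers (each cell type counted once), the weight is
#' `w_g = 1 - (n_g - 1) / (N - 1)` (and 1 when `N = 1`): 1 for a
#' uniquely-marking gene, 0 for a ubiquitous one, linear in between.
#'
#' @param db a [marker_db()].
#' @param tissue tissue label present in `db`.
#' @return a `specificity_weights` tibble with columns `gene`, `n_cell_types`
#'   (how many cell types list the gene) and `weight`, covering exactly the
#'   union of the tissue's marker genes; attributes `tissue` and
#'   `n_cell_types` (the tissue's N).
#' @examples
#' db <- marker_db("T", c("A", "B"), list(c("G1", "G2"), "G2"))
#' compute_specificity_weights(db, "T")
#' @export
compute_specificity_weights <- function(db, tissue) {
  sub <- db_tissue_entries(db, tissue)
  n_types <- nrow(sub)
  membership <- purrr::map(seq_len(n_types), function(i) {
    union(sub$positive_genes[[i]], sub$negative_genes[[i]])
  })
  counts <- table(unlist(membership))
  genes <- sort(names(counts))
  n_g <- as.integer(counts[genes])
  w <- if (n_types > 1) 1 - (n_g - 1) / (n_types - 1) else rep(1, length(genes))
  out <- tibble::tibble(gene = genes, n_cell_types = n_g, weight = w)
  attr(out, "tissue") <- tissue
  attr(out, "n_cell_types") <- n_types
  class(out) <- c("specificity_weights", class(out))
  out
}

weights_as_vector <- function(w) {
  setNames(w$weight, w$gene)
}

#' Marker-panel coverage against a gene universe
#'
#' Targeted platforms measure only a few hundred genes; when that panel
#' misses the marker genes, marker-based annotation degrades or fails
#' outright. This report quantifies, per cell type, how many of its database
#' markers are detectable in a given gene universe (e.g. the probe panel or
#' the genes actually measured in a dataset).
#'
#' @param db a [marker_db()].
#' @param tissue tissue label present in `db`.
#' @param gene_universe character vector of gene symbols available in the
#'   data; canonicalized before matching.
#' @return a `coverage_report` tibble, one row per cell type in lexicographic
#'   order, with columns `cell_type`, `n_positive_in_db`,
#'   `n_positive_detected`, `n_negative_in_db`, `n_negative_detected` and
#'   `fraction_detected` (detected / in-database over positives and
#'   negatives together); attributes `genes_in_universe` and
#'   `db_genes_detected`.
#' @export
marker_coverage_report <- function(db, tissue, gene_universe) {
  if (length(gene_universe) == 0) {
    abort_validation("gene_universe must be non-empty")
  }
  universe <- canonicalize_genes(gene_universe)
  sub <- db_tissue_entries(db, tissue)
  sub <- sub[order(sub$cell_type), , drop = FALSE]
  rows <- purrr::map(seq_len(nrow(sub)), function(i) {
    pos <- sub$positive_genes[[i]]
    neg <- sub$negative_genes[[i]]
    pos_det <- length(intersect(pos, universe))
    neg_det <- length(intersect(neg, universe))
    tibble::tibble(
      cell_type = sub$cell_type[i],
      n_positive_in_db = length(pos),
      n_positive_detected = pos_det,
      n_negative_in_db = length(neg),
      n_negative_detected = neg_det,
      fraction_detected = (pos_det + neg_det) / (length(pos) + length(neg))
    )
  })
  out <- dplyr::bind_rows(rows)
  db_genes <- unique(unlist(c(sub$positive_genes, sub$negative_genes)))
  attr(out, "genes_in_universe") <- length(universe)
  attr(out, "db_genes_detected") <- length(intersect(db_genes, universe))
  class(out) <- c("coverage_report", class(out))
  out
}

#' Write a coverage report as TSV
#' @param report a `coverage_report` from [marker_coverage_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage_report <- function(report, path) {
  readr::write_tsv(as.data.frame(report), path, progress = FALSE)
  invisible(path)
}

#' Derive a marker database from labelled reference profiles
#'
#' Builds positive marker sets from reference expression (for example
#' cluster-averaged single-cell profiles) when no curated panel exists. For
#' each label `k` and gene `g` the score is
#' `s(g, k) = mean log1p expression in k - max mean over all other labels`;
#' the top `top_n` genes with `s > 0` become `k`'s positive markers (ties
#' broken by lexicographic gene symbol). Negative sets are left empty —
#' curating reliable negative markers needs domain knowledge a mean
#' difference cannot supply.
#'
#' Labels for which no gene scores positive (e.g. expression identical across
#' labels) are omitted from the result with a warning.
#'
#' @param expr a [spot_matrix()] of reference profiles (genes x
#'   cells/clusters), layer `counts` or `normalized`.
#' @param labels named character vector mapping every column of `expr` to a
#'   cell-type label; at least 2 distinct labels.
#' @param top_n number of positive markers to keep per label; when fewer
#'   genes score positive, all available are taken with a warning.
#' @param tissue tissue label to record in the resulting database.
#' @return a [marker_db()].
#' @export
derive_markers_from_reference <- function(expr, labels, top_n, tissue) {
  stopifnot(inherits(expr, "spot_matrix"))
  spots <- spot_ids(expr)
  if (is.null(names(labels))) {
    if (length(labels) != length(spots)) {
      abort_validation("labels must be named by column id or match the column count")
    }
    names(labels) <- spots
  }
  missing <- setdiff(spots, names(labels))
  if (length(missing) > 0) {
    abort_validation(sprintf("no label for reference column(s): %s",
                             paste(head(missing, 3), collapse = ", ")))
  }
  labels <- as.character(labels[spots])
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    abort_validation("derive_markers_from_reference needs >= 2 distinct labels")
  }
  L <- log1p(as.matrix(expr$values))
  class_means <- vapply(classes, function(k) {
    rowMeans(L[, labels == k, drop = FALSE])
  }, numeric(nrow(L)))
  genes <- gene_ids(expr)
  entries <- purrr::map(classes, function(k) {
    other <- class_means[, colnames(class_means) != k, drop = FALSE]
    s <- class_means[, k] - apply(other, 1, max)
    keep <- which(s > 0)
    ord <- keep[order(-s[keep], genes[keep])]
    markers <- genes[head(ord, top_n)]
    if (length(markers) < top_n) {
      warn(sprintf(
        "label '%s': only %d gene(s) score positive (top_n = %d requested)",
        k, length(markers), top_n
      ))
    }
    markers
  })
  names(entries) <- classes
  keep <- lengths(entries) > 0
  marker_db(
    tissue = rep(tissue, sum(keep)),
    cell_type = classes[keep],
    positive_genes = entries[keep]
  )
}
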