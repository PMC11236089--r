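#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a score matrix into long format
#'
#' @param x a `sctype_scores` object.
#' @param ... unused.
#' @return a tibble with one row per (cell type, spot): columns `cell_type`,
#'   `spot_id`, `score`.
#' @export
tidy.sctype_scores <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "cell_type") |>
    tidyr::pivot_longer(-"cell_type", names_to = "spot_id", values_to = "score")
}

#' One-row summary of a score matrix
#'
#' @param x a `sctype_scores` object.
#' @param ... unused.
#' @return a one-row tibble: `n_cell_types` (scored), `n_excluded` (no
#'   detected markers), `n_spots`, `tissue`.
#' @export
glance.sctype_scores <- function(x, ...) {
  tibble::tibble(
    n_cell_types = nrow(x$scores),
    n_excluded = sum(x$markers_used$n_pos_used + x$markers_used$n_neg_used == 0),
    n_spots = ncol(x$scores),
    tissue = x$tissue
  )
}

#' Per-class rows of a benchmark report
#' @param x a `benchmark_report`.
#' @param ... unused.
#' @return the per-class tibble, without report attributes.
#' @export
tidy.benchmark_report <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' One-row summary of a benchmark report
#' @param x a `benchmark_report`.
#' @param ... unused.
#' @return one-row tibble: `median_f1`, `n_classes`, `n_spots`.
#' @export
glance.benchmark_report <- function(x, ...) {
  tibble::tibble(
    median_f1 = attr(x, "median_f1"),
    n_classes = nrow(x),
    n_spots = attr(x, "n_spots")
  )
}

#' Tidy a marker database into one row per marker gene
#' @param x a `marker_db`.
#' @param ... unused.
#' @return tibble with columns `tissue`, `cell_type`, `gene`, `direction`
#'   (`"positive"`/`"negative"`).
#' @export
tidy.marker_db <- function(x, ...) {
  pos <- tidyr::unnest(
    dplyr::mutate(x[, c("tissue", "cell_type", "positive_genes")],
                  direction = "positive"),
    cols = "positive_genes", names_repair = "minimal")
  names(pos)[names(pos) == "positive_genes"] <- "gene"
  neg <- tidyr::unnest(
    dplyr::mutate(x[, c("tissue", "cell_type", "negative_genes")],
                  direction = "negative"),
    cols = "negative_genes", names_repair = "minimal")
  names(neg)[names(neg) == "negative_genes"] <- "gene"
  dplyr::arrange(dplyr::bind_rows(pos, neg),
                 .data$tissue, .data$cell_type, .data$direction, .data$gene)
}

#' @importFrom rlang .data
NULL
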