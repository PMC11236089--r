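#' Log-transform and z-score marker genes across spots
#'
#' Restricts the matrix to the marker genes of interest, applies `log1p`,
#' then centres and scales each gene across spots (sample sd, `n - 1`
#' denominator). Z-scoring puts every marker on the tissue-average scale so
#' positive and negative markers contribute symmetrically to the enrichment
#' score. Genes with zero variance across spots carry no signal and are
#' dropped with a message.
#'
#' @param expr a [spot_matrix()] with layer `counts` or `normalized`.
#' @param gene_subset character vector of gene symbols to retain (typically
#'   the union of the marker panel); canonicalized before matching.
#' @return a [spot_matrix()] with layer `zscored`, rows restricted to the
#'   retained marker genes.
#' @export
zscore_normalize <- function(expr, gene_subset) {
  stopifnot(inherits(expr, "spot_matrix"))
  if (expr$layer == "zscored") {
    abort_validation("expr is already z-scored")
  }
  if (length(gene_subset) == 0) {
    abort_validation("gene_subset must be non-empty")
  }
  genes <- intersect(canonicalize_genes(gene_subset), gene_ids(expr))
  if (length(genes) == 0) {
    abort_no_overlap("no marker genes detected in data")
  }
  L <- log1p(as.matrix(expr$values[genes, , drop = FALSE]))
  s <- apply(L, 1, sd)
  flat <- s == 0 | is.na(s)
  if (any(flat)) {
    inform(sprintf("dropping %d zero-variance marker gene(s): %s",
                   sum(flat), paste(head(genes[flat], 5), collapse = ", ")))
    L <- L[!flat, , drop = FALSE]
    s <- s[!flat]
  }
  if (nrow(L) == 0) {
    abort_validation("all marker genes have zero variance across spots")
  }
  Z <- (L - rowMeans(L)) / s
  spot_matrix(Z, layer = "zscored")
}

#' Marker-set enrichment scores per cell type and spot
#'
#' The core scoring step: each spot's z-scored marker profile is summarized
#' into one enrichment score per candidate cell type. For cell type `k` with
#' detected positive markers `P_k` and negative markers `N_k` (each
#' intersected with the matrix's genes), the score at spot `s` is
#'
#' \deqn{ES(k, s) = \frac{\sum_{g \in P_k} w_g z_{g,s} -
#'   \sum_{g \in N_k} w_g z_{g,s}}{\sqrt{|P_k| + |N_k|}}}
#'
#' where `w_g` is the gene's specificity weight. The square-root marker-count
#' normalizer makes scores comparable between cell types with marker panels
#' of different sizes. Cell types with no detected markers are excluded from
#' the score matrix and recorded with `(0, 0)` in `markers_used`.
#'
#' @param z a z-scored [spot_matrix()] (see [zscore_normalize()]).
#' @param db a [marker_db()].
#' @param tissue tissue label present in `db`.
#' @param w specificity weights from [compute_specificity_weights()] for the
#'   same tissue; computed from `db` when omitted.
#' @return a `sctype_scores` object holding the cell-type x spot score
#'   matrix, the spot/cell-type orderings and a `markers_used` tibble with
#'   the detected positive/negative marker counts per cell type.
#' @export
sctype_score <- function(z, db, tissue, w = NULL) {
  stopifnot(inherits(z, "spot_matrix"))
  if (z$layer != "zscored") {
    abort_validation("sctype_score requires a z-scored matrix; run zscore_normalize() first")
  }
  sub <- db_tissue_entries(db, tissue)
  if (is.null(w)) w <- compute_specificity_weights(db, tissue)
  if (!identical(attr(w, "tissue"), tissue)) {
    abort_validation("specificity weights were computed for a different tissue")
  }
  wv <- weights_as_vector(w)
  genes <- gene_ids(z)
  Z <- as.matrix(z$values)

  used <- tibble::tibble(
    cell_type = sub$cell_type,
    n_pos_used = integer(nrow(sub)),
    n_neg_used = integer(nrow(sub))
  )
  score_rows <- vector("list", nrow(sub))
  for (i in seq_len(nrow(sub))) {
    pos <- intersect(sub$positive_genes[[i]], genes)
    neg <- intersect(sub$negative_genes[[i]], genes)
    used$n_pos_used[i] <- length(pos)
    used$n_neg_used[i] <- length(neg)
    n_mark <- length(pos) + length(neg)
    if (n_mark == 0) next
    contrib <- numeric(ncol(Z))
    if (length(pos) > 0) contrib <- contrib + colSums(wv[pos] * Z[pos, , drop = FALSE])
    if (length(neg) > 0) contrib <- contrib - colSums(wv[neg] * Z[neg, , drop = FALSE])
    score_rows[[i]] <- contrib / sqrt(n_mark)
  }
  keep <- !vapply(score_rows, is.null, logical(1))
  if (!any(keep)) {
    abort_no_overlap("no marker genes detected in data")
  }
  scores <- do.call(rbind, score_rows[keep])
  dimnames(scores) <- list(sub$cell_type[keep], spot_ids(z))
  structure(
    list(scores = scores, cell_types = sub$cell_type[keep],
         spot_ids = spot_ids(z), markers_used = used, tissue = tissue),
    class = "sctype_scores"
  )
}

#' @export
print.sctype_scores <- function(x, ...) {
  cat(sprintf("<sctype_scores> %d cell types x %d spots (tissue: %s)\n",
              nrow(x$scores), ncol(x$scores), x$tissue))
  dropped <- x$markers_used$cell_type[
    x$markers_used$n_pos_used + x$markers_used$n_neg_used == 0]
  if (length(dropped) > 0) {
    cat("  excluded (no detected markers):", paste(dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

annotation_result <- function(tbl, mode) {
  attr(tbl, "mode") <- mode
  class(tbl) <- c("spot_annotation", class(tbl))
  tbl
}

top_two <- function(scores) {
  # Per column: argmax with lexicographic tie-break, runner-up, margin.
  labels <- rownames(scores)
  ord <- order(labels)
  scores <- scores[ord, , drop = FALSE]
  labels <- labels[ord]
  purrr::map(seq_len(ncol(scores)), function(j) {
    x <- scores[, j]
    i1 <- which.max(x)  # first max = lexicographically smallest label
    if (length(x) > 1) {
      rest <- x[-i1]
      i2 <- which.max(rest)
      list(label = labels[i1], top = x[i1],
           runner_up = labels[-i1][i2], margin = x[i1] - rest[i2])
    } else {
      list(label = labels[i1], top = x[i1],
           runner_up = NA_character_, margin = NA_real_)
    }
  })
}

#' Assign a cell-type label to every spot
#'
#' Each spot gets the cell type with the maximum enrichment score; exact ties
#' go to the lexicographically smallest label so results are deterministic
#' across platforms. When `unknown_if_nonpositive` is set (the default), a
#' spot whose best score is not positive — i.e. no cell type's markers are
#' enriched above the tissue average — is labelled `"Unknown"` rather than
#' force-assigned.
#'
#' @param em a `sctype_scores` object from [sctype_score()].
#' @param unknown_if_nonpositive label a spot `"Unknown"` when its top score
#'   is <= 0.
#' @return a `spot_annotation` tibble with columns `spot_id`,
#'   `assigned_label`, `top_score`, `runner_up` and `margin`
#'   (top minus runner-up score; `NA` with a single candidate cell type).
#' @export
assign_spots <- function(em, unknown_if_nonpositive = TRUE) {
  stopifnot(inherits(em, "sctype_scores"))
  picks <- top_two(em$scores)
  out <- tibble::tibble(
    spot_id = em$spot_ids,
    assigned_label = purrr::map_chr(picks, "label"),
    top_score = purrr::map_dbl(picks, "top"),
    runner_up = purrr::map_chr(picks, "runner_up"),
    margin = purrr::map_dbl(picks, "margin")
  )
  if (unknown_if_nonpositive) {
    out$assigned_label[out$top_score <= 0] <- "Unknown"
  }
  annotation_result(out, mode = "spot")
}

#' Assign cell-type labels per cluster of spots
#'
#' Spots are often clustered before annotation; aggregating scores over a
#' cluster pools weak per-spot signal. Scores are summed over member spots,
#' the cluster label is the argmax (lexicographic tie-break), and a cluster
#' whose top summed score falls below `min_score_fraction` times its spot
#' count is labelled `"Unknown"` — a confidence cutoff scaled to cluster
#' size. Every member spot inherits the cluster's label.
#'
#' @param em a `sctype_scores` object.
#' @param cluster_of named vector mapping every spot id in `em` to a cluster
#'   id.
#' @param min_score_fraction `"Unknown"` threshold as a fraction of cluster
#'   size; default 0.25.
#' @return a `spot_annotation` tibble with columns `spot_id`, `cluster_id`,
#'   `assigned_label`, `top_score` (cluster-summed), `runner_up`, `margin`.
#' @export
assign_clusters <- function(em, cluster_of, min_score_fraction = 0.25) {
  stopifnot(inherits(em, "sctype_scores"))
  missing <- setdiff(em$spot_ids, names(cluster_of))
  if (length(missing) > 0) {
    abort_validation(sprintf("spot(s) missing from cluster_of: %s",
                             paste(head(missing, 3), collapse = ", ")))
  }
  cl <- as.character(cluster_of[em$spot_ids])
  clusters <- sort(unique(cl))
  ind <- vapply(clusters, function(k) as.numeric(cl == k),
                numeric(length(cl)))
  summed <- em$scores %*% ind  # cell types x clusters
  colnames(summed) <- clusters
  picks <- top_two(summed)
  n_spots <- as.integer(table(cl)[clusters])
  label <- purrr::map_chr(picks, "label")
  top <- purrr::map_dbl(picks, "top")
  label[top < min_score_fraction * n_spots] <- "Unknown"
  cluster_tbl <- tibble::tibble(
    cluster_id = clusters,
    assigned_label = label,
    top_score = top,
    runner_up = purrr::map_chr(picks, "runner_up"),
    margin = purrr::map_dbl(picks, "margin"),
    n_spots = n_spots
  )
  idx <- match(cl, clusters)
  out <- tibble::tibble(
    spot_id = em$spot_ids,
    cluster_id = cl,
    assigned_label = cluster_tbl$assigned_label[idx],
    top_score = cluster_tbl$top_score[idx],
    runner_up = cluster_tbl$runner_up[idx],
    margin = cluster_tbl$margin[idx]
  )
  out <- annotation_result(out, mode = "cluster")
  attr(out, "clusters") <- cluster_tbl
  out
}
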