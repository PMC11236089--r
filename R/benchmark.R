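#' Cell-type taxonomy
#'
#' A rooted forest of cell-type labels used for hierarchy-aware scoring: a
#' prediction counts as correct when it matches the ground-truth label at
#' the same or a deeper taxonomy level. For example, with ground truth
#' "Immune cell", predictions "T cell", "Dendritic cell" or "B cell" are all
#' correct, while "Stromal" is not.
#'
#' @param parent named character vector mapping each child label to its
#'   parent; root labels are simply absent from the names.
#' @return a `cell_taxonomy` object.
#' @examples
#' tax <- cell_taxonomy(c("T cell" = "Immune cell", "B cell" = "Immune cell"))
#' is_correct("T cell", "Immune cell", tax)
#' @export
cell_taxonomy <- function(parent) {
  parent <- setNames(as.character(parent), names(parent))
  if (length(parent) > 0 && (is.null(names(parent)) || any(!nzchar(names(parent))))) {
    abort_validation("parent map must be named by child label")
  }
  if (anyDuplicated(names(parent))) {
    abort_validation("each label may have only one parent")
  }
  # forest check: every label must reach a root in < 100 steps
  for (lab in union(names(parent), parent)) {
    cur <- lab
    for (step in seq_len(100)) {
      if (!cur %in% names(parent)) break
      cur <- parent[[cur]]
      if (step == 100) abort_validation(
        sprintf("taxonomy has a cycle or depth >= 100 at label '%s'", lab))
    }
  }
  structure(list(parent = parent), class = "cell_taxonomy")
}

#' Read a taxonomy from a two-column child/parent TSV
#' @param path TSV path with columns `child`, `parent` (header optional).
#' @return a [cell_taxonomy()].
#' @export
read_taxonomy <- function(path) {
  first <- strsplit(readr::read_lines(path, n_max = 1), "\t")[[1]]
  has_header <- identical(tolower(first[1:2]), c("child", "parent"))
  tbl <- readr::read_tsv(path, col_names = if (has_header) TRUE else c("child", "parent"),
                         col_types = "cc", progress = FALSE)
  cell_taxonomy(setNames(tbl$parent, tbl$child))
}

taxonomy_labels <- function(tax) union(names(tax$parent), tax$parent)

# self + ancestors, nearest first
ancestry_chain <- function(label, tax) {
  chain <- label
  cur <- label
  while (cur %in% names(tax$parent)) {
    cur <- tax$parent[[cur]]
    chain <- c(chain, cur)
  }
  chain
}

# one-shot log per unseen predicted label, per call chain
log_unseen <- function(labels, seen_env) {
  new <- setdiff(labels, ls(seen_env))
  if (length(new) > 0) {
    for (l in new) assign(l, TRUE, envir = seen_env)
    inform(sprintf("predicted label(s) not in taxonomy: %s",
                   paste(new, collapse = ", ")))
  }
}

#' Hierarchy-aware correctness of a prediction
#'
#' `TRUE` iff the prediction equals the truth or the truth is a proper
#' ancestor of the prediction (same-or-deeper taxonomy level). Predictions
#' absent from the taxonomy are incorrect (logged once per unseen label).
#' Vectorized over `pred`/`truth` pairs.
#'
#' @param pred predicted label(s).
#' @param truth ground-truth label(s), recycled against `pred`.
#' @param tax a [cell_taxonomy()].
#' @return logical vector.
#' @export
is_correct <- function(pred, truth, tax) {
  n <- max(length(pred), length(truth))
  pred <- rep_len(as.character(pred), n)
  truth <- rep_len(as.character(truth), n)
  known <- taxonomy_labels(tax)
  seen <- new.env(parent = emptyenv())
  vapply(seq_len(n), function(i) {
    if (pred[i] == truth[i]) return(TRUE)
    if (!pred[i] %in% known) {
      log_unseen(pred[i], seen)
      return(FALSE)
    }
    truth[i] %in% ancestry_chain(pred[i], tax)[-1]
  }, logical(1))
}

#' Lift predictions to a common taxonomy level
#'
#' Tool comparisons are biased when tools predict at different taxonomic
#' depths; unification lifts each prediction to its nearest ancestor
#' (including itself) within the ground-truth label set. Predictions with no
#' such ancestor map to `"Other"`.
#'
#' @param preds named character vector (spot -> predicted label).
#' @param tax a [cell_taxonomy()].
#' @param truth_level_labels the set of labels predictions are unified into.
#' @return named character vector of unified labels, same names as `preds`.
#' @export
unify_labels <- function(preds, tax, truth_level_labels) {
  uniq <- unique(as.character(preds))
  lifted <- vapply(uniq, function(p) {
    chain <- ancestry_chain(p, tax)
    hit <- chain[chain %in% truth_level_labels]
    if (length(hit) > 0) hit[1] else "Other"
  }, character(1))
  setNames(lifted[as.character(preds)], names(preds))
}

#' Benchmark predictions against ground truth
#'
#' Inner-joins predictions and truths on spot id, drops spots whose truth is
#' `"Empty"` or `"Unknown"` (unassignable ground truth), unifies predictions
#' to the truth label set via [unify_labels()], and computes one-vs-rest
#' TP/FP/FN, precision, recall and F1 per truth class plus the median F1
#' across classes (even class counts use the mean of the two central
#' values). `"Unknown"` predictions are never correct: they count as a false
#' negative for the truth class.
#'
#' @param preds named character vector (spot -> predicted label).
#' @param truths named character vector (spot -> true label).
#' @param tax a [cell_taxonomy()].
#' @return a `benchmark_report` tibble, one row per truth class in
#'   lexicographic order, columns `class`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`; attribute `median_f1`.
#' @export
evaluate_annotations <- function(preds, truths, tax) {
  common <- intersect(names(preds), names(truths))
  dropped <- length(preds) + length(truths) - 2 * length(common)
  if (dropped > 0) {
    inform(sprintf("%d spot(s) present in only one of preds/truths; dropped", dropped))
  }
  if (length(common) == 0) {
    abort_validation("preds and truths share no spot ids")
  }
  p <- as.character(preds[common])
  t <- as.character(truths[common])
  keep <- !t %in% c("Empty", "Unknown")
  p <- p[keep]
  t <- t[keep]
  if (length(t) == 0) {
    abort_validation("no spots with assignable ground truth")
  }
  classes <- sort(unique(t))
  p <- unname(unify_labels(setNames(p, seq_along(p)), tax, classes))
  rows <- purrr::map(classes, function(k) {
    tp <- sum(p == k & t == k)
    fp <- sum(p == k & t != k)
    fn <- sum(p != k & t == k)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(class = k, tp = tp, fp = fp, fn = fn,
                   precision = prec, recall = rec, f1 = f1)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "median_f1") <- median(out$f1)
  attr(out, "n_spots") <- length(t)
  class(out) <- c("benchmark_report", class(out))
  out
}

#' Median F1 of a benchmark report
#' @param report a `benchmark_report`.
#' @return the median of the per-class F1 scores.
#' @export
median_f1 <- function(report) attr(report, "median_f1")

#' Write a benchmark report as TSV
#'
#' One row per class plus a summary row `__median__` carrying the median F1.
#'
#' @param report a `benchmark_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_report <- function(report, path) {
  out <- as.data.frame(report)
  out <- rbind(out, data.frame(class = "__median__", tp = NA, fp = NA, fn = NA,
                               precision = NA, recall = NA,
                               f1 = attr(report, "median_f1")))
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}
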