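# Shared fixtures, all built in code.

brain_db <- function() {
  marker_db(
    tissue = rep("Brain", 3),
    cell_type = c("Astrocyte", "Neuron", "Oligodendrocyte"),
    positive_genes = list(c("GFAP", "AQP4"), c("RBFOX3", "SYT1"), c("MBP", "PLP1")),
    negative_genes = list(character(0), "GFAP", character(0))
  )
}

write_db_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("tissueType\tcellName\tgeneSymbolmore1\tgeneSymbolmore2", rows), path)
  path
}

# small deterministic counts matrix with named dims
toy_counts <- function(values, genes, spots) {
  spot_matrix(matrix(values, nrow = length(genes),
                     dimnames = list(genes, spots)), layer = "counts")
}

# immune-centred toy taxonomy used across benchmark tests
immune_taxonomy <- function() {
  cell_taxonomy(c(
    "T cell" = "Immune cell",
    "B cell" = "Immune cell",
    "Dendritic cell" = "Immune cell",
    "CD4 T cell" = "T cell",
    "Stromal" = "Non-immune",
    "Endothelial" = "Non-immune"
  ))
}

# Brute-force reference for the enrichment score: explicit loops over
# (cell type, spot, gene), kept independent of the vectorized implementation.
oracle_sctype_score <- function(Z, db, tissue, w) {
  sub <- db[db$tissue == tissue, ]
  wv <- setNames(w$weight, w$gene)
  out <- list()
  for (i in seq_len(nrow(sub))) {
    pos <- intersect(sub$positive_genes[[i]], rownames(Z))
    neg <- intersect(sub$negative_genes[[i]], rownames(Z))
    if (length(pos) + length(neg) == 0) next
    row <- numeric(ncol(Z))
    for (s in seq_len(ncol(Z))) {
      acc <- 0
      for (g in pos) acc <- acc + wv[[g]] * Z[g, s]
      for (g in neg) acc <- acc - wv[[g]] * Z[g, s]
      row[s] <- acc / sqrt(length(pos) + length(neg))
    }
    out[[sub$cell_type[i]]] <- row
  }
  m <- do.call(rbind, out)
  colnames(m) <- colnames(Z)
  m
}

# random scoring instance: z-scored matrix + random marker db + weights
random_scoring_instance <- function(n_genes = 20, n_spots = 10, n_types = 4,
                                    with_negative = TRUE) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  Z <- matrix(rnorm(n_genes * n_spots), nrow = n_genes,
              dimnames = list(genes, sprintf("s%02d", seq_len(n_spots))))
  Z <- t(scale(t(Z)))  # exact z-scores so the layer invariant holds
  pos <- lapply(seq_len(n_types), function(i) sample(genes, sample(2:5, 1)))
  neg <- lapply(seq_len(n_types), function(i) {
    if (!with_negative) return(character(0))
    sample(setdiff(genes, pos[[i]]), sample(0:3, 1))
  })
  db <- marker_db(tissue = rep("Sim", n_types),
                  cell_type = sprintf("CT%d", seq_len(n_types)),
                  positive_genes = pos, negative_genes = neg)
  w <- compute_specificity_weights(db, "Sim")
  list(Z = Z, z = spot_matrix(Z, layer = "zscored"), db = db, w = w)
}

# run the standard annotate pipeline on a simulated tissue
annotate_simulation <- function(sim, db = planted_marker_db(sim$config),
                                tissue = "Simulated") {
  panel <- unique(unlist(c(db$positive_genes, db$negative_genes)))
  z <- suppressMessages(zscore_normalize(sim$spot_matrix, panel))
  em <- sctype_score(z, db, tissue)
  assign_spots(em)
}

recovery_accuracy <- function(sim, ann) {
  truth <- setNames(sim$truth$true_label, sim$truth$spot_id)
  ne <- names(truth)[truth != "Empty"]
  mean(ann$assigned_label[match(ne, ann$spot_id)] == truth[ne])
}
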