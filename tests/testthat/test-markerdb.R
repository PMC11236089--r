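test_that("TSV parsing canonicalizes, dedupes and filters by tissue", {
  path <- write_db_tsv(c(
    "Brain\tAstrocyte\tGFAP,AQP4\t",
    "Brain\tNeuron\tgfap , Gfap ,RBFOX3\tMBP",
    "Liver\tHepatocyte\tALB\t"
  ))
  db <- load_marker_db(path)
  expect_s3_class(db, "marker_db")
  expect_equal(nrow(db), 3)
  astro <- db[db$cell_type == "Astrocyte", ]
  expect_setequal(astro$positive_genes[[1]], c("GFAP", "AQP4"))
  expect_length(astro$negative_genes[[1]], 0)
  # case-fold + dedupe within one list
  neuron <- db[db$cell_type == "Neuron", ]
  expect_equal(neuron$positive_genes[[1]], c("GFAP", "RBFOX3"))

  brain <- load_marker_db(path, tissue_filter = "Brain")
  expect_equal(sort(brain$cell_type), c("Astrocyte", "Neuron"))
  expect_true(all(brain$tissue == "Brain"))
})

test_that("malformed marker files raise classed errors naming the problem", {
  no_col <- tempfile(fileext = ".tsv")
  writeLines(c("tissueType\tcellName\tgeneSymbolmore1",
               "Brain\tAstrocyte\tGFAP"), no_col)
  expect_error(load_marker_db(no_col), "geneSymbolmore2",
               class = "spottype_format_error")

  dup <- write_db_tsv(c("Brain\tAstrocyte\tGFAP\t", "Brain\tAstrocyte\tAQP4\t"))
  expect_error(load_marker_db(dup), "Astrocyte",
               class = "spottype_validation_error")

  both <- write_db_tsv("Brain\tAstrocyte\tGFAP,AQP4\tGFAP")
  err <- expect_error(load_marker_db(both), class = "spottype_validation_error")
  expect_match(conditionMessage(err), "GFAP")
  expect_match(conditionMessage(err), "Astrocyte")

  no_pos <- write_db_tsv("Brain\tAstrocyte\t\tGFAP")
  expect_error(load_marker_db(no_pos), "no positive",
               class = "spottype_validation_error")
})

test_that("specificity weights follow the linear sharing formula", {
  # N = 5 cell types; a gene in n of them gets w = 1 - (n-1)/(N-1)
  genes_of <- list(c("U", "S3", "ALL"), c("S3", "ALL"), c("S3", "ALL"),
                   c("ALL"), c("ALL"))
  db <- marker_db(tissue = rep("T", 5), cell_type = paste0("C", 1:5),
                  positive_genes = genes_of)
  w <- compute_specificity_weights(db, "T")
  wv <- setNames(w$weight, w$gene)
  expect_identical(wv[["U"]], 1)      # unique marker
  expect_identical(wv[["ALL"]], 0)    # ubiquitous marker
  expect_identical(wv[["S3"]], 0.5)   # 1 - (3-1)/(5-1)
  expect_true(all(w$weight >= 0 & w$weight <= 1))
  # exactly the union of the tissue's marker genes is covered
  expect_setequal(w$gene, c("U", "S3", "ALL"))
})

test_that("negative-list membership counts toward sharing, once per cell type", {
  db <- marker_db(
    tissue = rep("T", 3), cell_type = c("A", "B", "C"),
    positive_genes = list("G1", "G2", "G3"),
    negative_genes = list("G2", character(0), "G2")
  )
  w <- compute_specificity_weights(db, "T")
  wv <- setNames(w$weight, w$gene)
  # G2: positive in B, negative in A and C -> n_g = 3 of N = 3
  expect_identical(wv[["G2"]], 0)
  expect_identical(wv[["G1"]], 1)
})

test_that("weights are strictly decreasing in sharing and invariant to relabeling", {
  n_types <- 6
  for (trial in 1:5) {
    set.seed(100 + trial)
    # cell type i lists genes G_i..G_n, so gene G_k is shared by k cell types
    pos <- lapply(seq_len(n_types), function(i) sprintf("G%d", i:n_types))
    db <- marker_db(tissue = rep("T", n_types),
                    cell_type = paste0("C", seq_len(n_types)),
                    positive_genes = pos)
    w <- compute_specificity_weights(db, "T")
    ord <- w[order(w$n_cell_types), ]
    expect_true(all(diff(ord$weight) < 0))

    perm <- sample(n_types)
    db2 <- marker_db(tissue = rep("T", n_types),
                     cell_type = paste0("C", seq_len(n_types))[perm],
                     positive_genes = pos[perm])
    w2 <- compute_specificity_weights(db2, "T")
    expect_equal(w2[order(w2$gene), ], w[order(w$gene), ], ignore_attr = TRUE)
  }
})

test_that("unknown tissue raises a lookup error", {
  expect_error(compute_specificity_weights(brain_db(), "Kidney"),
               class = "spottype_lookup_error")
  expect_error(marker_coverage_report(brain_db(), "Kidney", "GFAP"),
               class = "spottype_lookup_error")
})

test_that("coverage report counts detected markers against the universe", {
  db <- marker_db(tissue = c("T", "T"), cell_type = c("A", "B"),
                  positive_genes = list(c("A1", "B1", "C1", "D1"), c("E1", "F1")),
                  negative_genes = list(character(0), c("G1", "H1")))

  full <- marker_coverage_report(db, "T", c("A1","B1","C1","D1","E1","F1","G1","H1"))
  expect_equal(full$fraction_detected, c(1, 1))

  none <- marker_coverage_report(db, "T", c("ZZ1", "ZZ2"))
  expect_equal(none$n_positive_detected, c(0, 0))
  expect_equal(none$fraction_detected, c(0, 0))

  # positives {A1,B1,C1,D1}, universe {A1,B1,X} -> 2 detected, fraction 0.5
  partial <- marker_coverage_report(db, "T", c("A1", "B1", "X"))
  row_a <- partial[partial$cell_type == "A", ]
  expect_equal(row_a$n_positive_detected, 2)
  expect_equal(row_a$fraction_detected, 0.5)

  # rows are ordered lexicographically and totals ignore universe order/dupes
  expect_equal(partial$cell_type, sort(partial$cell_type))
  shuffled <- marker_coverage_report(db, "T", c("X", "B1", "A1", "a1", "B1"))
  expect_equal(as.data.frame(shuffled), as.data.frame(partial))
  expect_equal(attr(shuffled, "db_genes_detected"), 2)
})

test_that("marker derivation ranks genes by mean log1p margin over the best other class", {
  genes <- c("GA", "GB", "GC", "GD", "GE", "GF")
  cells <- sprintf("c%d", 1:9)
  labels <- setNames(rep(c("L1", "L2", "L3"), each = 3), cells)
  # deterministic counts, 3 profiles per label
  vals <- rbind(
    GA = c(9, 10, 11, 0, 0, 0, 0, 1, 0),   # strong L1 marker
    GB = c(4, 5, 6, 1, 1, 1, 0, 0, 0),     # weaker L1 marker
    GC = c(0, 0, 0, 8, 9, 10, 0, 0, 0),    # strong L2 marker
    GD = c(2, 2, 2, 2, 2, 2, 2, 2, 2),     # flat
    GE = c(0, 0, 0, 0, 0, 1, 7, 8, 9),     # strong L3 marker
    GF = c(1, 0, 1, 3, 4, 3, 0, 1, 1)      # weaker L2 marker
  )
  expr <- toy_counts(vals, genes, cells)

  # independent oracle: explicit means on log1p counts
  L <- log1p(vals)
  s <- sapply(c("L1", "L2", "L3"), function(k) {
    mk <- rowMeans(L[, labels == k])
    mo <- apply(sapply(setdiff(c("L1","L2","L3"), k),
                       function(o) rowMeans(L[, labels == o])), 1, max)
    mk - mo
  })
  expected <- lapply(c("L1", "L2", "L3"), function(k) {
    sc <- s[, k]
    keep <- names(sc)[sc > 0]
    head(keep[order(-sc[keep], keep)], 2)
  })

  db <- suppressWarnings(
    derive_markers_from_reference(expr, labels, top_n = 2, tissue = "Toy"))
  expect_equal(db$positive_genes, expected)
  expect_true(all(lengths(db$negative_genes) == 0))
})

test_that("a gene dominant in one label becomes its sole marker", {
  expr <- toy_counts(c(5, 0, 0, 5, 0, 0,
                       0, 0, 3, 0, 0, 3),
                     genes = c("DOM", "OTH"),
                     spots = c("a1", "a2", "b1", "b2", "c1", "c2"))
  labels <- setNames(c("A", "A", "B", "B", "C", "C"),
                     c("a1", "a2", "b1", "b2", "c1", "c2"))
  db <- suppressWarnings(
    derive_markers_from_reference(expr, labels, top_n = 1, tissue = "Toy"))
  expect_equal(db$positive_genes[db$cell_type == "A"][[1]], "DOM")
})

test_that("identical expression across labels yields no markers, with a warning", {
  expr <- toy_counts(rep(c(2, 3), 4), genes = c("G1", "G2"),
                     spots = sprintf("c%d", 1:4))
  labels <- setNames(c("A", "A", "B", "B"), sprintf("c%d", 1:4))
  w <- capture_warnings(
    db <- derive_markers_from_reference(expr, labels, top_n = 2, tissue = "Toy"))
  expect_match(w, "score positive", all = TRUE)
  expect_length(w, 2)  # one warning per markerless label
  expect_equal(nrow(db), 0)
})

test_that("derivation needs at least two labels", {
  expr <- toy_counts(1:4, c("G1", "G2"), c("c1", "c2"))
  expect_error(
    derive_markers_from_reference(expr, c(c1 = "A", c2 = "A"), 1, "Toy"),
    class = "spottype_validation_error"
  )
})

test_that("derivation on noiseless type profiles recovers the planted blocks", {
  cfg <- simulation_config(n_cells = 12, seed = 3)
  # noiseless reference: one profile per type, markers high, background low
  profiles <- sapply(cfg$cell_types, function(t) {
    mu <- rep(cfg$mu_low, length(cfg$genes))
    mu[cfg$genes %in% cfg$marker_blocks[[t]]] <- cfg$mu_high
    mu
  })
  rownames(profiles) <- cfg$genes
  expr <- spot_matrix(profiles, layer = "normalized")
  db <- derive_markers_from_reference(
    expr, setNames(cfg$cell_types, cfg$cell_types),
    top_n = cfg$markers_per_type, tissue = "Sim")
  for (t in cfg$cell_types) {
    expect_setequal(db$positive_genes[db$cell_type == t][[1]],
                    cfg$marker_blocks[[t]])
  }
})

test_that("marker databases round-trip through TSV", {
  db <- brain_db()
  path <- tempfile(fileext = ".tsv")
  write_marker_db(db, path)
  back <- load_marker_db(path)
  expect_equal(as.data.frame(back[order(back$cell_type), ]),
               as.data.frame(db[order(db$cell_type), ]))
})

test_that("tidy() flattens a marker database to one row per gene", {
  long <- tidy(brain_db())
  expect_equal(nrow(long), 7)
  expect_setequal(long$gene[long$direction == "negative"], "GFAP")
})
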