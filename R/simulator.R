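#' Configuration for the 2D tissue simulator
#'
#' The simulator emulates a tissue of spatially organized cell types probed
#' by fixed-diameter capture spots: typed cells are placed on a 2D micron
#' grid, each cell expresses genes from an overdispersed count model, and a
#' square lattice of spots captures the cells lying within each spot's
#' radius. Each cell type has a disjoint "planted" block of marker genes
#' expressed at mean `mu_high`, while all other genes sit at background mean
#' `mu_low`; counts are negative binomial with dispersion `theta`
#' (`var = mu + mu^2 / theta`).
#'
#' Defaults describe a moderately easy instance: 4 cell types in spatially
#' coherent territories (`blobs`), 5 markers each, a strong high/low
#' contrast (10 vs 0.2), 2000 cells on a 500 x 500 micron field and 10
#' micron spots on a 20 micron pitch (so capture disks are disjoint and each
#' cell is seen by at most one spot). The `blobs` default reflects what the
#' generator emulates: real tissues organize cell types into spatial
#' domains, so most spots capture cells of one type; `random` mixes types
#' everywhere and puts an intrinsic ceiling on per-spot accuracy because a
#' spot capturing two cells of different types has an arbitrary
#' (tie-broken) majority label.
#'
#' @param width_um,height_um field extents in microns.
#' @param n_cells number of cells to place.
#' @param cell_types ordered character vector of type labels (K >= 2).
#' @param layout spatial organisation of types: `"random"` (iid uniform),
#'   `"stripes"` (K equal-width vertical bands) or `"blobs"` (Gaussian
#'   territories around jittered grid centres).
#' @param markers_per_type size of each type's planted marker block.
#' @param n_background_genes extra genes with background expression in every
#'   type.
#' @param mu_high,mu_low NB means for a type's own markers vs all other
#'   genes; `mu_high > mu_low >= 0`.
#' @param theta NB dispersion (size) parameter, > 0; larger is closer to
#'   Poisson.
#' @param spot_diameter_um capture-spot diameter (default 10).
#' @param spot_pitch_um lattice pitch between spot centres; must be at least
#'   `spot_diameter_um / 2`.
#' @param seed master seed; stage-specific substreams are derived from it.
#' @return a `simulation_config` list with a `marker_blocks` map (type ->
#'   planted marker genes) and the full `genes` vector.
#' @export
simulation_config <- function(width_um = 500, height_um = 500, n_cells = 2000,
                              cell_types = paste0("Type", 1:4),
                              layout = c("blobs", "random", "stripes"),
                              markers_per_type = 5, n_background_genes = 30,
                              mu_high = 10, mu_low = 0.2, theta = 2,
                              spot_diameter_um = 10, spot_pitch_um = 20,
                              seed = 1L) {
  layout <- match.arg(layout)
  if (length(cell_types) < 2) abort_validation("need at least 2 cell types")
  if (anyDuplicated(cell_types)) abort_validation("cell_types must be unique")
  if (!(mu_high > mu_low) || mu_low < 0) abort_validation("need mu_high > mu_low >= 0")
  if (theta <= 0) abort_validation("theta must be > 0")
  if (spot_pitch_um < spot_diameter_um / 2) {
    abort_validation("spot_pitch_um must be >= spot_diameter_um / 2")
  }
  k <- length(cell_types)
  marker_blocks <- purrr::map(seq_len(k), function(i) {
    sprintf("MK%d_%02d", i, seq_len(markers_per_type))
  })
  names(marker_blocks) <- cell_types
  genes <- c(unlist(marker_blocks, use.names = FALSE),
             sprintf("BG_%03d", seq_len(n_background_genes)))
  structure(
    list(width_um = width_um, height_um = height_um, n_cells = n_cells,
         cell_types = cell_types, layout = layout,
         markers_per_type = markers_per_type, marker_blocks = marker_blocks,
         genes = genes, mu_high = mu_high, mu_low = mu_low, theta = theta,
         spot_diameter_um = spot_diameter_um, spot_pitch_um = spot_pitch_um,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Marker database of the planted simulation markers
#'
#' Converts a simulation's planted marker blocks into a [marker_db()] so the
#' scoring pipeline can be run on simulated data with a matched panel.
#'
#' @param config a [simulation_config()].
#' @param tissue tissue label to record; default `"Simulated"`.
#' @return a [marker_db()] with one entry per simulated cell type.
#' @export
planted_marker_db <- function(config, tissue = "Simulated") {
  marker_db(
    tissue = rep(tissue, length(config$cell_types)),
    cell_type = config$cell_types,
    positive_genes = config$marker_blocks
  )
}

#' Place typed cells on the 2D field
#'
#' Positions are uniform over the rectangle. Types follow the layout:
#' `random` assigns each cell iid-uniformly over the K types; `stripes`
#' splits the field into K equal-width vertical bands and types each cell by
#' its band; `blobs` scatters K territory centres on a jittered grid and
#' types each cell by its nearest centre. Deterministic given the seed.
#'
#' @param config a [simulation_config()].
#' @param seed placement seed; defaults to a substream of `config$seed`.
#' @return tibble with columns `cell_id`, `x_um`, `y_um`, `type`.
#' @export
place_cells <- function(config, seed = substream_seed(config$seed, 1)) {
  k <- length(config$cell_types)
  if (k > config$n_cells && config$n_cells > 0) {
    abort_validation("more cell types than cells")
  }
  n <- config$n_cells
  set.seed(seed)
  x <- runif(n, 0, config$width_um)
  y <- runif(n, 0, config$height_um)
  type <- switch(config$layout,
    random = config$cell_types[sample.int(k, n, replace = TRUE)],
    stripes = {
      band <- pmin(floor(x / (config$width_um / k)), k - 1)
      config$cell_types[band + 1]
    },
    blobs = {
      ncol_g <- ceiling(sqrt(k))
      nrow_g <- ceiling(k / ncol_g)
      gx <- (seq_len(ncol_g) - 0.5) / ncol_g * config$width_um
      gy <- (seq_len(nrow_g) - 0.5) / nrow_g * config$height_um
      centers <- expand.grid(x = gx, y = gy)[seq_len(k), ]
      jitter_scale <- 0.1 * min(config$width_um / ncol_g, config$height_um / nrow_g)
      centers$x <- centers$x + runif(k, -jitter_scale, jitter_scale)
      centers$y <- centers$y + runif(k, -jitter_scale, jitter_scale)
      d2 <- outer(x, centers$x, "-")^2 + outer(y, centers$y, "-")^2
      config$cell_types[max.col(-d2, ties.method = "first")]
    }
  )
  tibble::tibble(cell_id = sprintf("cell_%05d", seq_len(n)),
                 x_um = x, y_um = y, type = type)
}

#' Draw per-cell expression counts
#'
#' Counts are independent negative binomial per (gene, cell): mean `mu_high`
#' when the gene belongs to the cell's type's planted marker block,
#' `mu_low` otherwise; dispersion `theta` throughout. Deterministic given
#' the seed.
#'
#' @param placements output of [place_cells()].
#' @param config a [simulation_config()].
#' @param seed expression seed; defaults to a substream of `config$seed`.
#' @return a [spot_matrix()] (genes x cells, layer `counts`) whose columns
#'   are the cell ids.
#' @export
draw_expression <- function(placements, config,
                            seed = substream_seed(config$seed, 2)) {
  genes <- config$genes
  n_genes <- length(genes)
  n <- nrow(placements)
  set.seed(seed)
  counts <- matrix(0L, nrow = n_genes, ncol = n,
                   dimnames = list(genes, placements$cell_id))
  for (t in config$cell_types) {
    cols <- which(placements$type == t)
    if (length(cols) == 0) next
    mu <- rep(config$mu_low, n_genes)
    mu[genes %in% config$marker_blocks[[t]]] <- config$mu_high
    draws <- rnbinom(n_genes * length(cols), size = config$theta, mu = mu)
    counts[, cols] <- matrix(draws, nrow = n_genes)
  }
  spot_matrix(counts, layer = "counts")
}

spot_lattice <- function(config) {
  pitch <- config$spot_pitch_um
  cx <- seq(pitch / 2, config$width_um, by = pitch)
  cy <- seq(pitch / 2, config$height_um, by = pitch)
  grid <- expand.grid(col = seq_along(cx) - 1L, row = seq_along(cy) - 1L)
  spot_geometry(
    barcode = sprintf("spot_%03d_%03d", grid$row, grid$col),
    in_tissue = TRUE,
    array_row = grid$row, array_col = grid$col,
    x_um = cx[grid$col + 1L], y_um = cy[grid$row + 1L],
    spot_diameter_um = config$spot_diameter_um
  )
}

#' Probe placed cells with a lattice of capture spots
#'
#' Spot centres sit on a square lattice with pitch `spot_pitch_um` covering
#' the field. A cell is captured by a spot iff its centre lies within
#' `spot_diameter_um / 2` of the spot centre (closed disk); with overlapping
#' disks the nearest spot wins, so each cell is captured at most once, and
#' with pitch >= diameter the disks are disjoint (asserted). Spot counts are
#' the gene-wise sum over captured cells. The ground-truth label of a spot
#' is the modal type among its captured cells (lexicographic tie-break);
#' spots capturing no cell are labelled `"Empty"`.
#'
#' @param placements output of [place_cells()].
#' @param cell_expr output of [draw_expression()].
#' @param config a [simulation_config()].
#' @return a `simulated_tissue` list: `cells`, `cell_expr`, `spots`
#'   (geometry), `capture` (spot -> captured cell ids), `spot_matrix`,
#'   `truth` (tibble: `spot_id`, `true_label`, `n_cells_captured`).
#' @export
probe_spots <- function(placements, cell_expr, config) {
  spots <- spot_lattice(config)
  pitch <- config$spot_pitch_um
  radius <- config$spot_diameter_um / 2
  # nearest lattice centre by index arithmetic
  col <- pmin(pmax(round((placements$x_um - pitch / 2) / pitch), 0),
              max(spots$array_col))
  row <- pmin(pmax(round((placements$y_um - pitch / 2) / pitch), 0),
              max(spots$array_row))
  dx <- placements$x_um - (pitch / 2 + col * pitch)
  dy <- placements$y_um - (pitch / 2 + row * pitch)
  captured <- sqrt(dx^2 + dy^2) <= radius + 1e-9
  if (pitch >= config$spot_diameter_um && any(captured)) {
    # disjoint disks: a captured cell must not lie within radius of any
    # neighbouring spot centre
    d_other <- pmin(sqrt((pitch - abs(dx))^2 + dy^2),
                    sqrt(dx^2 + (pitch - abs(dy))^2))
    stopifnot(all(d_other[captured] >= radius - 1e-9))
  }
  spot_of <- ifelse(captured, sprintf("spot_%03d_%03d", row, col), NA_character_)

  n_spot <- nrow(spots)
  idx <- match(spot_of, spots$barcode)
  counts <- matrix(0, nrow = nrow(cell_expr$values), ncol = n_spot,
                   dimnames = list(gene_ids(cell_expr), spots$barcode))
  cap_idx <- which(!is.na(idx))
  if (length(cap_idx) > 0) {
    ind <- Matrix::sparseMatrix(i = cap_idx, j = idx[cap_idx], x = 1,
                                dims = c(nrow(placements), n_spot))
    counts <- as.matrix(cell_expr$values %*% ind)
    dimnames(counts) <- list(gene_ids(cell_expr), spots$barcode)
  }

  truth <- purrr::map_chr(seq_len(n_spot), function(j) {
    types <- placements$type[which(idx == j)]
    if (length(types) == 0) return("Empty")
    tab <- table(types)
    names(tab)[tab == max(tab)][1]  # table names are sorted: lexicographic tie-break
  })
  capture <- split(placements$cell_id[cap_idx], spots$barcode[idx[cap_idx]])
  capture <- capture[intersect(spots$barcode, names(capture))]

  structure(
    list(
      cells = placements,
      cell_expr = cell_expr,
      spots = spots,
      capture = capture,
      spot_matrix = spot_matrix(counts, layer = "counts"),
      truth = tibble::tibble(
        spot_id = spots$barcode, true_label = truth,
        n_cells_captured = as.integer(tabulate(idx[cap_idx], nbins = n_spot))
      ),
      config = config
    ),
    class = "simulated_tissue"
  )
}

#' @export
print.simulated_tissue <- function(x, ...) {
  cat(sprintf(
    "<simulated_tissue> %d cells (%d types), %d genes, %d spots (%d non-empty)\n",
    nrow(x$cells), length(x$config$cell_types), length(x$config$genes),
    nrow(x$spots), sum(x$truth$true_label != "Empty")
  ))
  invisible(x)
}

#' Run the full simulation pipeline
#'
#' Places cells, draws expression, and probes spots under one seed schedule
#' (substreams of `config$seed`), optionally writing the standard on-disk
#' formats: an MTX bundle, a tissue positions CSV, and `truth.tsv`
#' (`spot_id`, `true_label`, `n_cells_captured`).
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory to write outputs into.
#' @return a `simulated_tissue` (see [probe_spots()]).
#' @export
simulate_tissue <- function(config, out_dir = NULL) {
  placements <- place_cells(config)
  cell_expr <- draw_expression(placements, config)
  sim <- probe_spots(placements, cell_expr, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mtx_bundle(sim$spot_matrix, out_dir)
    write_tissue_positions(sim$spots, file.path(out_dir, "tissue_positions.csv"))
    readr::write_tsv(sim$truth, file.path(out_dir, "truth.tsv"), progress = FALSE)
  }
  sim
}
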