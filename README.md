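# spottype

Deconvolution-free, marker-based cell-type annotation for spatial
transcriptomics spots.

Spot-based platforms (Visium, Slide-seq) measure the convolved expression of
the cells under each fixed-diameter capture spot. The dominant way to label
such spots is reference-based deconvolution, which is computationally heavy
and needs a matched single-cell atlas. When the assay detects a large enough
gene panel, a much lighter route works: score every spot directly against
curated sets of positive and negative marker genes and assign the
highest-scoring cell type. `spottype` implements that route end to end, for
analysts who have a spot count matrix and a marker panel (curated or derived
from reference profiles) but no atlas: the scoring engine, the marker
database tooling, coverage diagnostics for targeted panels, a 2D tissue
simulator with per-spot ground truth, and taxonomy-aware benchmarking.

## The score

For a tissue with $N$ candidate cell types, each gene $g$ in the marker panel
gets a specificity weight

$$w_g = 1 - \frac{n_g - 1}{N - 1},$$

where $n_g$ is the number of cell types listing $g$ among their positive or
negative markers: a gene that marks a single cell type gets weight 1, a
ubiquitous one weight 0. Raw counts are `log1p`-transformed and z-scored
per gene across spots ($z_{g,s}$). The enrichment of cell type $k$ with
detected positive markers $P_k$ and negative markers $N_k$ at spot $s$ is

$$ES(k,s) = \frac{\sum_{g \in P_k} w_g\, z_{g,s} \;-\; \sum_{g \in N_k} w_g\, z_{g,s}}{\sqrt{|P_k| + |N_k|}},$$

and the spot's label is $\arg\max_k ES(k,s)$, or `"Unknown"` when no score is
positive. A cluster mode sums scores over caller-provided clusters with a
size-scaled confidence cutoff. Negative markers let a cell type be penalized
for expressing genes it should lack, which sharpens calls for closely
related types.

Benchmarking is hierarchy-aware: a prediction is correct when it matches the
truth at the same or a deeper level of a cell-type taxonomy (truth "Immune
cell" accepts "T cell", "B cell" or "Dendritic cell", rejects "Stromal"),
and per-class precision/recall/F1 are summarized by the median F1.

## Worked example

Simulate a tissue of four cell types in spatial territories, probed by 10 µm
spots on a 20 µm lattice, then annotate it with its planted marker panel and
benchmark against the per-spot ground truth:

```r
library(spottype)

cfg <- simulation_config(seed = 11)   # 2000 cells, 4 types, 500x500 um
sim <- simulate_tissue(cfg)
sim
#> <simulated_tissue> 2000 cells (4 types), 50 genes, 625 spots (307 non-empty)

db <- planted_marker_db(cfg)
z  <- zscore_normalize(sim$spot_matrix, unique(unlist(db$positive_genes)))
em <- sctype_score(z, db, "Simulated")
ann <- assign_spots(em)
head(ann[ann$assigned_label != "Unknown", ], 3)
#> # A tibble: 3 x 5
#>   spot_id      assigned_label top_score runner_up margin
#>   <chr>        <chr>              <dbl> <chr>      <dbl>
#> 1 spot_000_003 Type1               6.85 Type2       6.34
#> 2 spot_000_006 Type1               8.48 Type3       7.81
#> 3 spot_000_008 Type1               4.85 Type3       4.73

truth <- setNames(sim$truth$true_label, sim$truth$spot_id)
report <- evaluate_annotations(setNames(ann$assigned_label, ann$spot_id),
                               truth, cell_taxonomy(character(0)))
glance(report)
#> # A tibble: 1 x 3
#>   median_f1 n_classes n_spots
#>       <dbl>     <int>   <int>
#> 1         1         4     307
```

`top_score` is the winning enrichment score, `margin` its lead over the
runner-up cell type — small margins flag ambiguous spots. Here every one of
the 307 cell-bearing spots is labelled with its true type (median F1 = 1);
with weaker expression contrast or mixed-type spots the report shows exactly
which cell types degrade. `plot_spot_labels(ann, sim$spots)` draws the
labels at their slide coordinates, and `autoplot(report)` plots the
per-class metrics.

The same pipeline runs from the shell via the installed launcher
(`system.file("cli", "spottype", package = "spottype")`) with subcommands
`simulate`, `annotate`, `coverage`, `derive-markers` and `benchmark`.

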