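---
title: "Marker-based annotation of spatial transcriptomics spots: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based annotation of spatial transcriptomics spots: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spottype)
```

# The problem and the model

A capture spot on a Visium- or Slide-seq-style slide reports the summed
transcripts of every cell it overlaps. Deconvolution methods unmix that
signal against a single-cell reference atlas; `spottype` takes the
deconvolution-free route: it asks, per spot, which cell type's marker
signature the measured profile most resembles, using nothing but curated
positive and negative marker gene sets. This works when the platform detects
enough genes that the marker panel is well covered, and it identifies the
*predominant* cell type of a spot rather than per-type proportions — both
points are discussed under limitations.

The scoring pipeline has three steps.

**Normalization.** Counts restricted to the marker panel are
`log1p`-transformed and each gene is centred and scaled across spots (sample
standard deviation, $n-1$ denominator). The resulting $z_{g,s}$ measures how
far spot $s$ sits above or below the tissue-average expression of gene $g$.
Z-scoring is what makes negative markers meaningful: a below-average
negative marker contributes positively to its cell type's score, symmetric
to an above-average positive marker. Genes with zero variance across spots
carry no discriminative signal and are dropped (with a message). If *no*
panel gene is present in the data at all — the situation a small targeted
probe panel creates — normalization fails hard with a dedicated error class
rather than silently scoring nothing; the CLI maps this to exit code 3.

**Specificity weights.** With $N$ cell types in the selected tissue and
$n_g$ of them listing gene $g$ among their positive or negative markers
(each cell type counted once, other tissues ignored), the weight is

$$w_g = 1 - \frac{n_g-1}{N-1}, \qquad w_g = 1 \text{ when } N = 1 .$$

This is the simplest form with the right endpoints — weight 1 for a gene
marking exactly one cell type, weight 0 for one marking all of them — and
strictly decreasing in between. Membership in a negative list counts toward
$n_g$: a gene that one type must express and another must lack is shared
evidence, and sharing is what the weight discounts. Both choices were design
decisions; the linear form is not the only defensible rescaling, but any
monotone alternative changes scores smoothly and never the endpoint
behaviour.

**Enrichment and assignment.** For cell type $k$ with detected positive set
$P_k$ and negative set $N_k$,

$$ES(k,s) = \frac{\sum_{g\in P_k} w_g z_{g,s} - \sum_{g\in N_k} w_g z_{g,s}}{\sqrt{|P_k| + |N_k|}} .$$

The $\sqrt{|P_k|+|N_k|}$ normalizer keeps cell types with different
marker-set sizes comparable: under independent unit-variance contributions
the denominator equalizes score variance, so a type with 30 markers holds no
mechanical advantage over one with 5. Cell types with no detected marker are
excluded from the score matrix (and recorded), not scored as zero. Each spot
takes the argmax; exact ties go to the lexicographically smallest label so
results are platform-independent.

# Tunable parameters

- `unknown_if_nonpositive` (default `TRUE`, `assign_spots`): a spot whose
  best score is ≤ 0 shows no marker set enriched above tissue average, and
  force-assigning it would manufacture a label from noise. Abstention is the
  conservative default; disable it to force a call everywhere.
- `min_score_fraction` (default 0.25, `assign_clusters`): in cluster mode,
  scores are summed over member spots and a cluster is `"Unknown"` when its
  top summed score is below `min_score_fraction ×` (cluster size). Scaling
  the cutoff by cluster size makes it a per-spot average-confidence
  threshold, so large clusters are not harder to label than small ones. Both
  spot and cluster modes are provided because practice varies; spot mode is
  the default pipeline.
- `um_per_px` (default 1, `read_tissue_positions`): position files store
  full-resolution pixel coordinates; the scale converts them to microns.
  Geometry follows the image convention (origin top-left, y downward,
  0-based).
- `top_n` (`derive_markers_from_reference`): markers kept per label. The
  derivation rule is deliberately simple — on `log1p` means, score each gene
  by its margin over the *best* other label and keep the top `top_n` with
  positive margin (lexicographic tie-break). Using the best-other-label
  margin (rather than the mean of others) guarantees a selected marker is
  highest in its own label, which is the property the scorer relies on. It
  is not a differential-expression test and makes no significance claim;
  negative sets are left for manual curation.

# What the simulator emulates

`simulation_config()` describes a rectangular field of typed cells probed by
a square lattice of fixed-diameter capture spots:

- **Geometry.** Cells are uniform in the rectangle; spot centres sit on a
  lattice with pitch `spot_pitch_um` (default 20 µm) and a cell is captured
  by the nearest spot centre within `spot_diameter_um / 2` (default 10 µm
  diameter, closed disk — a cell at exactly the radius is captured). With
  pitch ≥ diameter the disks are disjoint, each cell is seen at most once
  (asserted), and gene-wise counts are conserved between captured cells and
  the spot matrix — an invariant the tests check on random configurations.
- **Spatial organisation.** The default layout `blobs` (Gaussian-style
  territories around jittered grid centres) reflects what the generator is
  meant to emulate: real tissues organize cell types into spatial domains,
  so most spots capture cells of a single type. `stripes` gives sharp
  straight boundaries; `random` intermixes types completely. Under `random`,
  a spot that captures two cells of different types has a coin-flip majority
  label resolved lexicographically, which places an intrinsic ceiling on
  per-spot accuracy that no annotator can cross — useful as a stress test,
  misleading as a default.
- **Expression.** Counts are negative binomial per (gene, cell) — the
  standard overdispersed model for transcript counts — with mean `mu_high`
  (default 10) for the cell's own planted marker block and `mu_low` (default
  0.2) elsewhere, dispersion `theta` (default 2, variance
  $\mu + \mu^2/\theta$). Defaults describe a clearly separated tissue of
  2000 cells, 4 types and 5 disjoint markers per type on 500 × 500 µm;
  shrinking `mu_high/mu_low` toward 1 is the difficulty dial, and a test
  asserts recovery accuracy degrades monotonically along that ladder.
- **Ground truth.** A spot's label is the modal captured type
  (lexicographic tie-break); cell-free spots are `"Empty"` and excluded from
  evaluation.

Per-spot truth plus the planted marker database make the full pipeline
testable end to end with no external data. What the simulator does *not*
model: capture-efficiency gradients and dropout, segmentation or diffusion
noise between adjacent spots, doublet chemistry, correlated gene modules,
and platform-specific probe chemistry (a gene-subset filter on the output
stands in for targeted panels). Passing the recovery tests therefore shows
the scoring machinery is correct and well-calibrated on cleanly separated
signatures — not that real tissues of arbitrary complexity will annotate at
the same accuracy.

# Benchmarking semantics

Ground-truth labels often sit at a coarser taxonomic level than predictions,
so exact string match would punish a *more* specific correct call. The
taxonomy (a parent-map forest, depth-checked) defines correctness as
same-or-deeper: truth "Immune cell" accepts "T cell" and, transitively, any
descendant. For aggregate metrics, predictions are first *unified* — lifted
to their nearest ancestor within the truth label set, with `"Other"` as the
fallback — then scored one-vs-rest per truth class. Conventions, each a
deliberate choice: zero-denominator precision/recall are 0 (not NA), the
median over an even number of classes is the mean of the two central values,
`"Unknown"` predictions are always wrong (a false negative for the truth
class, a false positive for none), and spots whose *truth* is `"Empty"` or
`"Unknown"` are excluded since no prediction could be scored against them.

# Numerical and degenerate-input choices

- All gene symbols are uppercased on ingest everywhere (database, matrices,
  panels), so case differences never cause silent marker loss.
- Sparse matrices are accepted and densified only after restriction to the
  marker panel, which is small relative to the transcriptome.
- The spot-capture boundary uses a 10⁻⁹ µm tolerance so the closed-disk rule
  is stable against floating-point rounding of lattice arithmetic.
- A reference label with no positive-margin gene yields no database entry
  (plus a warning) rather than an entry with an empty marker set, which the
  database validator rejects by design.
- Seed schedule: the master seed spawns fixed substreams for placement and
  expression, so each stage is independently reproducible and a
  whole-pipeline run is byte-identical across repeats (tested against the
  on-disk outputs).
- Test and example problem sizes — 20 genes × 10 spots × 4 types for the
  scoring oracle, a few hundred to 2000 cells for simulations, 5 replicate
  seeds for recovery — are chosen so the full suite exercises every code
  path in seconds while keeping binomial/NB sampling noise well inside the
  asserted margins.

# Known limitations

- The method identifies the predominant cell type per spot or cluster; it
  does not estimate mixture proportions, and in tissue where spots routinely
  straddle several types a deconvolution method answers a question this tool
  does not.
- Accuracy is bounded by marker coverage: on targeted panels that miss the
  marker genes the pipeline refuses to run (by design), and
  `marker_coverage_report()` should be consulted before trusting results on
  any panel-limited platform.
- Specificity weights are computed within the selected tissue only;
  cross-tissue marker sharing is deliberately ignored.
- The linear weight and the √-count integration are principled
  reconstructions of marker-set enrichment practice, not the only options;
  both are isolated in small functions should a user want to experiment.
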