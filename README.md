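# spotsplit

Same-section integration of imaging-based spatial proteomics (CODEX-style
multiplexed immunofluorescence, cell-level) with sequencing-based spatial
transcriptomics acquired on a deterministic-barcoding spot grid (DBiT-seq
style, spot-level).

Barcoded spots are 20–50 µm squares containing several cells each, so spot
counts mix cell types. When the same tissue section is subsequently imaged,
every spot's cellular content is directly observable. `spotsplit` turns that
observation into a deconvolution: it registers the imaging coordinate system
onto the spot grid, counts the annotated cells inside each spot footprint to
obtain cell-type proportions, and splits each spot's gene counts into
pure-cell-type sub-spots.

With $x_{ij}$ the count of gene $j$ in spot $i$, $\beta_{ki}$ the fraction of
type-$k$ cells among the cells assigned to spot $i$, and $\mu_{kj}$ the mean
expression of gene $j$ in type $k$ from an scRNA-seq reference:

$$\hat X_{ijk} = x_{ij}\,\frac{\beta_{ki}\,\mu_{kj}}{\sum_{k'}\beta_{k'i}\,\mu_{k'j}}$$

so $\sum_k \hat X_{ijk} = x_{ij}$ exactly, and each (spot, type) pair becomes
a pure sub-spot usable in multimodal embeddings (e.g. weighted-nearest-
neighbor analyses) together with the matching protein sub-spots.

The package provides, as composable functions plus a chained pipeline:

* **Imaging features** — per-cell feature extraction from label masks and
  channel stacks, size/nuclear QC filters, [0, 1] quantile scaling.
* **Registration** — tissue-mask detection (Gaussian / Otsu / hole filling /
  largest component), similarity-transform estimation minimizing squared mask
  mismatch, intensity and spot-count polish stages, landmark affine fitting.
* **Deconvolution** — half-open footprint cell-to-spot assignment, count-based
  proportions, signature aggregation, the sub-spot splitting above, protein
  sub-spot aggregation.
* **Annotation** — linked-feature screening, smoothed shared-SVD mutual-
  nearest-neighbor pivot matching, label transfer, SVM propagation with
  held-out F1.
* **QC metrics** — spatially binned cross-slice marker correlation, average
  silhouette width, adjusted Rand index.
* **Simulator** — synthetic tissues with full ground truth (positions, types,
  signatures, true per-spot proportions, exact perturbation transforms), used
  by the entire test suite.

## Worked example

```r
library(spotsplit)

ts    <- generate_tissue(n_cells = 6000, n_types = 4, n_genes = 200,
                         n_markers = 20, field_size = c(1100, 1100), seed = 12)
grid  <- grid_config(n_channels_a = 20, n_channels_b = 20,
                     channel_width = 50, pitch = 50, origin = c(75, 75))
spots <- render_spots(ts, grid, seed = 112)                  # 400 spots
codex <- render_codex(ts, seed = 212)
moved <- perturb_coordinates(codex, scale = 1.08, rotation_deg = 7,
                             translation = c(18, -12), center = c(550, 550))
ref   <- render_reference(ts, n_profiles = 2000, seed = 312)

cfg <- pipeline_config(cells = moved$cells, spots = spots,
                       reference = ref$counts, reference_labels = ref$labels,
                       alias_map = as.list(ts$marker_genes),
                       out_dir = "run12", seed = 7)
report <- run_pipeline(cfg)
report$stages$register$info[c("scale", "rotation_deg")]
#> $scale
#> [1] 0.9248766
#> $rotation_deg
#> [1] -6.853954
report$stages$annotate$info$macro_f1
#> [1] 1
```

The recovered transform is the inverse of the simulated perturbation
(1/1.08 = 0.9259, −7°) to within 0.1% scale and 0.15°. `run12/` now holds the
normalized cell table, propagated labels, the transform, `beta.csv` (the
spot-by-type proportion matrix), the sub-spot count matrix
(`subspots/subspots.mtx` + sidecars), protein sub-spots, QC scores and a
hashed run report; comparing `beta.csv` against the simulator's recorded
truth gives a mean absolute error of 0.042 per entry here.

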