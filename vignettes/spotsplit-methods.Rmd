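---
title: "Methods: CODEX-informed deconvolution of barcoded spatial transcriptomics spots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CODEX-informed deconvolution of barcoded spatial transcriptomics spots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotsplit)
```

## The problem

Deterministic barcoding in tissue (DBiT-seq style) delivers two orthogonal
sets of DNA barcodes through microfluidic channels, producing a grid of
square "spots" (20–50 µm) whose mRNA is sequenced. Each spot covers several
cells, so spot counts are mixtures over cell types. When the *same* section
is subsequently imaged with multiplexed immunofluorescence (CODEX-like
panels of ~25–50 protein markers), every spot's cellular content is directly
observable: segmented cells with centroids, areas, per-marker intensities —
and, after cross-modality annotation, cell-type labels.

`spotsplit` exploits this: instead of inferring spot composition from a
reference alone (RCTD/cell2location-style blind deconvolution), it **counts**
the registered, annotated imaging cells inside each spot footprint to get the
composition directly, then splits each spot's counts into pure-cell-type
sub-spots.

## The core model

Let $x_{ij}$ be the count of gene $j$ in spot $i$, $\beta_{ki}$ the fraction
of cells of type $k$ among the cells assigned to spot $i$, and $\mu_{kj}$
the mean expression of gene $j$ in type $k$ from an annotated scRNA-seq
reference. Each spot is split as

$$\hat X_{ijk} \;=\; x_{ij}\,
  \frac{\beta_{ki}\,\mu_{kj}}{\sum_{k'}\beta_{k'i}\,\mu_{k'j}}.$$

Properties the implementation guarantees and the tests verify:

* **Conservation** — $\sum_k \hat X_{ijk} = x_{ij}$ for every entry (to
  1e-9 relative; algebraically forced since the weights sum to 1).
* **Support** — $\hat X_{ijk} > 0$ only where $\beta_{ki} > 0$.
* **Per-gene scale invariance** — multiplying a column of $\mu$ by a
  positive constant cancels, so the reference's normalization does not
  matter gene-wise; per-type rescaling of $\mu$ is equivalent to
  reweighting $\beta$.
* **Degenerate genes** — if $\sum_{k'}\beta_{k'i}\mu_{k'j} = 0$ while
  $x_{ij} > 0$, the default `"beta"` policy splits by $\beta$ alone
  (conserving counts); `"drop"` routes such counts to an explicit
  unassigned bucket instead.

Cells map to spots by a **half-open square footprint**
$[c_x - w/2, c_x + w/2) \times [c_y - w/2, c_y + w/2)$ with $w$ the channel
width: footprints are disjoint whenever $w \le$ pitch, boundary behavior is
deterministic, and the simulator uses the same rule so ground truth and
pipeline agree exactly. $\beta$ uses unweighted cell counts (a centroid
either is or is not inside a footprint); area weighting is a possible
refinement we deliberately avoid because segmentation masks, not centroids,
would then be the honest geometry.

## Imaging feature extraction and QC

`extract_cell_features()` sums each channel under each segmentation label
(label 0 = background), with pixel-count areas and mean-pixel centroids.
`filter_cells()` retains cells within the [0.05, 0.95] area quantile range
(inclusive — "within") and with nuclear-stain signal strictly above its 0.1
quantile ("exceeding"); both use type-7 linear-interpolation quantiles, and
the applied thresholds are recorded so the retained set is reproducible.
`normalize_features()` divides by area (per-pixel mean intensity; a config
switch disables this), maps the 5th percentile to 0 and the 95th to 1 per
marker, and clips outside [0, 1]. A marker whose two quantiles coincide
carries no signal at this scaling and is set to 0 with a warning — the
convention consistent with clipping, chosen over NA to keep downstream
matrix operations total. The nuclear filter uses raw (not area-normalized)
signal, since filtering precedes scaling in the processing order.

## Registration

Both modalities are reduced to tissue masks: Gaussian smoothing, Otsu
threshold, binary hole filling, then the largest 8-connected component (so
debris does not distort the fit). `estimate_similarity_transform()` fits the
4-parameter similarity transform (scale, rotation, translation) minimizing
the squared mask mismatch over the fixed grid with nearest-neighbor
resampling, out-of-bounds as background. Initialization is moment-based
(centroids, area-ratio scale, principal-axis angle) with rotation expressed
about the moving centroid so rotation and translation decouple. Because the
principal axis is 180°-ambiguous — and nearly undefined for roundish
tissues — the simplex is multi-started from both axis orientations *and*
from the best basins of a coarse 5° angular scan; ties break toward the
smaller absolute angle. Refinement never returns a loss above its
initialization.

Binary masks carry only the outline, which limits cross-modality accuracy
to a few pixels. Two polish stages recover the rest:

1. `refine_similarity_intensity()` — squared error between the transformed
   imaging-density image and the spot-count image with a free linear
   intensity map (equivalently, maximal normalized cross-correlation),
   both images Gaussian-smoothed to the channel-pitch scale so the two
   renderings of tissue density become comparable. Bilinear sampling keeps
   sub-raster-pixel sensitivity; iterated simplex restarts avoid the
   degenerate collapsed simplices these flat surfaces induce.
2. `refine_similarity_spot_counts()` — the transform is polished against
   the barcoding grid itself: transformed cells are soft-binned into spot
   footprints (linear ramps, default 10 px, at footprint boundaries keep
   the objective smooth) and the correlation between predicted per-spot
   cell counts and observed per-spot totals is maximized. This objective
   is free of raster quantization and lattice artifacts and typically
   reaches ~1 px where image matching plateaus.

`estimate_affine_from_landmarks()` solves the least-squares affine for
manually paired marker points (≥3 non-collinear pairs; exact on noiseless
pairs), used when assessing imaging quality across adjacent slices.

Convention notes: coordinates are 0-based pixels, x = column, y = row;
rotations are counter-clockwise in the abstract y-up plane. Image-space
(y-down) interpretation flips the angle sign; all internal computations are
consistent, so this matters only when reporting angles.

## Cross-modality annotation

The annotation stage is a deliberately linear, deterministic stand-in for
iterative cross-modal matching frameworks (MaxFuse and kin), preserving
their pipeline role and stated parameters rather than their full machinery:

1. **Linked features** (`link_features()`): protein markers matched to
   genes by exact name plus an alias map (CD20 → MS4A1 and similar);
   pairs with standard deviation ≤ 0.01 in either modality are dropped
   (screening both sides and logging which failed).
2. **Smoothing** (`match_pivots()` step 1): each cell's linked-feature
   vector is moved toward the mean of its 15 nearest neighbors in the full
   feature space of its own modality, weight 0.3 — the weak-linkage
   smoothing recommended for this kind of integration; weight 0 is the
   identity.
3. **Shared reduction**: the standardized, smoothed linked features of both
   modalities are stacked and reduced by one SVD. The dimension default is
   the smallest count explaining ≥80% of variance **floored at 10**:
   smoothed linked features are highly collinear, so the variance rule
   alone can collapse to 2–3 components, which blurs minor populations
   into their neighbors.
4. **Pivots**: mutual nearest neighbors (within the 10-NN sets both ways)
   between reference profiles and imaging cells, at most one reference per
   cell. The match score is the negative match distance **divided by the
   cell's mean distance to its 10 nearest reference profiles**. With raw
   distances, the global top-fraction cut concentrates on whichever cell
   type forms the tightest expression cluster and can starve loose types
   entirely; the local-contrast ratio is label-free and lets all regions
   of the embedding compete on confidence rather than absolute density.
   The top 10% of imaging cells by score become pivots (fewer if the
   mutual-NN pool is smaller).
5. **Transfer + propagation** (`transfer_labels()`,
   `propagate_labels()`): pivot cells inherit their reference label; an
   SVM (radial kernel, balanced class weights) trained on pivot protein
   features labels all remaining cells. A stratified 80/20 pivot split
   yields per-class and macro F1 before the final refit on all pivots.

## QC metrics

`binned_marker_correlation()` quantifies cross-slice reproducibility: slice
A is transformed into slice B's frame, both are binned at 100 px
(`floor(coordinate / bin_size)`), per-bin marker means are correlated over
the common bins (≥3 required). Constant markers are reported `NA`, never 0,
to avoid deflating summaries. `average_silhouette_width()` (singletons
contribute 0) and `adjusted_rand_index()` score how well pure-cell-type
sub-spots separate in an embedding; both are checked against $O(n^2)$
brute-force implementations in the test suite.

## The simulator

`generate_tissue()` + `render_codex()` + `render_spots()` +
`render_reference()` produce paired datasets with complete ground truth
(positions, types, signatures, per-spot memberships and $\beta$, the exact
perturbation transform). The distributional choices are package choices —
the workflow's authors describe no generative model — and they are:

* RNA signatures: per-type gamma(0.3) profiles, rows normalized to
  expression proportions; the first `n_markers` genes are marker genes
  assigned round-robin to types and enriched 8-fold, plus ~3% private
  enriched genes per type. Spot counts are Poisson at 10⁴ expected counts
  per cell (so expected spot totals are depth × cell count).
* Protein signatures: proportional to the linked marker genes, plus an
  always-present DAPI-like channel; per-cell raw signal is
  `area × signature × lognormal` with the lognormal mean-calibrated to 1
  (CV 0.2 by default, additive background 0) so noiseless averages match
  signatures exactly.
* Geometry: cells in Gaussian niches (one per type, 65% own-type mixing)
  or uniform; lognormal areas around 80 px²; default densities of
  2 000–6 000 cells per ~1 mm² field (≈8–16 cells per 50 µm spot,
  low-normal for solid tissue).

What the simulator does **not** emulate: segmentation errors and doublets,
marker spillover and autofluorescence, spatial gradients in capture
efficiency, nonrigid tissue deformation between modalities (the true
mismatch is exactly a similarity transform), and reference batch effects.
Passing tests therefore validate the algorithms under their stated geometric
and statistical assumptions; they do not certify performance on real tissue,
where segmentation and deformation errors dominate.

## Numerical and design choices

* Optimizer: Nelder-Mead over (log scale, angle, tx, ty); iteration cap 500
  (mask stage) / 600–800 (polish stages); loss tolerance 1e-4 (masks,
  piecewise-constant loss) down to 1e-9 (smooth objectives); restarts as
  described. Refinement never worsens its initialization by construction.
* Sub-spot QC embedding: log1p of library-normalized sub-spot counts,
  PCA to 10 components; ARI compares k-means (k = number of types,
  seeded, 10 starts) with sub-spot type labels.
* Degenerate inputs have defined behavior throughout: empty masks,
  constant images, constant markers, empty spots, zero denominators,
  single-class pivots and collinear landmarks all raise errors or apply the
  documented convention rather than propagating NaNs.
* Pipeline outputs embed a provenance block (tool, version, seed) with no
  timestamp, so a rerun with the same config and seed is bit-identical —
  verified by hashing all outputs.

Validation problem sizes (chosen to exercise the statistical claims at desk
scale, stated here as the package's own test conditions): splitting
conservation on 100 random instances up to 50 spots × 200 genes × 6 types;
signature recovery on 500 spots × 200 genes × 4 types at depth 10⁴;
registration recovery over 50 random transforms (scale 0.8–1.2, |rotation| ≤
30°, |translation| ≤ 50 px) on a 300² simulator mask; annotation on 2 000
imaging cells vs 2 000 reference profiles; end-to-end on 6 000 cells, a
20 × 20 grid of 50 px spots and a known scale-1.08 / 7° / (18, −12) px
perturbation.

## Known limitations

* $\beta$ from centroids ignores cells straddling footprint boundaries;
  with ~19% of cells removed by the imaging QC filters, counting noise
  alone bounds per-entry $\beta$ accuracy at roughly 0.03–0.04 MAE for
  ~16-cell spots regardless of registration quality.
* The annotation stage assumes linked features carry enough signal to
  separate types after linear reduction; it does not iterate matching and
  embedding as full cross-modal integration frameworks do.
* Similarity registration cannot absorb nonrigid deformation; landmark
  affine estimation is provided for slice-to-slice comparison but the
  spot assignment always uses the similarity chain.
* Mask detection inherits Otsu's sensitivity to the foreground/background
  mix; images should be cropped to comparable fields before mask-based
  fitting (the spot-count polish is insensitive to this).

## A worked example

```{r example, eval = FALSE}
ts <- generate_tissue(n_cells = 3000, n_types = 4, n_genes = 200,
                      n_markers = 20, field_size = c(1100, 1100), seed = 1)
grid <- grid_config(n_channels_a = 20, n_channels_b = 20,
                    channel_width = 50, pitch = 50, origin = c(75, 75))
spots <- render_spots(ts, grid, seed = 2)
codex <- render_codex(ts, seed = 3)
moved <- perturb_coordinates(codex, scale = 1.05, rotation_deg = 5,
                             translation = c(15, -10), center = c(550, 550))
ref <- render_reference(ts, n_profiles = 2000, seed = 4)

cfg <- pipeline_config(cells = moved$cells, spots = spots,
                       reference = ref$counts, reference_labels = ref$labels,
                       alias_map = as.list(ts$marker_genes),
                       out_dir = "run", seed = 1)
report <- run_pipeline(cfg)
str(report$stages$qc$info)
```
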