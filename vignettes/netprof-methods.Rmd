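---
title: "netprof: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netprof: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprof)
```

This vignette documents the measurement conventions, the deliberate design
decisions, and the known limitations of the `netprof` pipeline. The worked
end-to-end example lives in the README; here the focus is on *why* each
stage computes what it computes.

## Pipeline overview

A run is a directory tree of Incucyte-style frames
(`Plate_Well_Field_00d00h00m` stems; 8-bit phase PNGs, 16-bit green/red
TIFFs) plus a `treatments.csv` well map. Each frame flows through:

1. pixel classification of the phase image into a Cells/Background
   probability map,
2. object segmentation (cells, DNA, Annexin V, NETs) with parent–child
   relations,
3. per-cell feature extraction,
4. five-class stage classification into per-image HitTables,
5. dynamics statistics over wells, treatments and time.

## Pixel classification

`extractPixelFeatures()` builds a 49-column filter bank: the raw intensity
plus Gaussian smoothings, gradient magnitudes, Laplacians, and
difference-of-Gaussians at seven scales (0.3–10 px), mirroring the standard
interactive-learning feature set. A 100-tree probability forest is trained
on sparse scribbles (`1` = cell, `2` = background). For synthetic scenes,
`scribbleFromTruth()` samples cell scribbles from eroded cell cores and
background scribbles *stratified by distance*: half from the 2–6 px ring
around cells, half from farther away. The ring stratum matters — phase
halos are the hardest background pixels, and a classifier never shown them
assigns them high P(cell), which bridges adjacent cells at segmentation
time.

## Segmentation conventions

- **Thresholding.** Otsu thresholds are computed on 256-bin histograms;
  `adaptiveOtsuThreshold()` interpolates per-tile thresholds (50-px tiles)
  bilinearly, multiplies by a correction factor, and clamps to bounds.
  Three-class variants fall back to the two-class cut when a tile has fewer
  than three populated grey levels.
- **DNA is thresholded in log space, bounded in raw space.**
  `thresholdDNA()` computes the adaptive Otsu cut on the
  `log2(1 + 255x)/8`-transformed image — where the faint-DNA mode is
  separable — then inverse-transforms the cut to the raw [0, 1] scale,
  where the 0.8 correction and the lower bound (default 0.01, useful range
  0.005–0.03) apply. Applying the bounds in log space would place them far
  above the fluorescence noise floor and admit large spurious background
  objects.
- **Background subtraction.** The fluorescence channels carry a constant
  camera/medium offset; `processFrame()` subtracts the per-frame median
  before preprocessing so the log gain amplifies signal, not offset.
- **Declumping.** Seeds are local maxima of the Gaussian-smoothed distance
  transform; dividing lines follow intensity gradients via constrained
  propagation. The smoothing size must match the object scale: the default
  10 px suits cells of roughly 20 px diameter and larger, while the
  synthetic scenes (7–14 px radii) use `declumpSmooth = 4`,
  `declumpTolerance = 0.3`. This is a scale parameter exposed to the user,
  not a tuning constant.
- **Size filters are inclusive** (`area >= minArea`,
  `area <= maxArea`) and pixel thresholds rescale with
  `(0.62 µm/px / pixelSize)^2` so the physical cut-offs are preserved:
  cells ≥ 15 px (≈ 5.8 µm² at 0.62 µm/px), DNA/Annexin objects 6–1000 px,
  NETs ≥ 150 px. The 6-px floor on fluorescence objects sits between
  shot-noise speckles (≤ 5 px) and real structures (> 50 px).
- **NETs** are DNA-positive 8-connected components of the *extracellular*
  region (cell pixels removed), expanded by 1 px so each touches its parent
  cell, size-filtered at 150 px, related to the maximum-overlap parent
  (ties to the lower label), and merged per parent. Extracellular DNA with
  no adjacent cell is not a NET.

## Feature families

One row per cell; 357 columns. Absent children produce `NA` features —
absence is not zero intensity — and `Children_count_*` columns carry the
absence explicitly.

- **Intensity**: max, min, mean, median, quartiles (type-7 interpolation),
  SD, and the *unscaled* MAD `median(|x − median(x)|)` (no 1.4826
  consistency factor).
- **Granularity**: a plain opening spectrum at disc radii 1–16 px, each
  entry the percentage of masked mean intensity removed at that scale,
  clipped monotone so entries are nonnegative and sum to ≤ 100. The
  subsampling/background-reconstruction refinements of some
  implementations are deliberately omitted.
- **Radial distribution**: signed distance to the parent-cell boundary,
  binned into four equal-width bins over the object's own range; `FracAtD`
  sums to 1, `MeanFrac` is 1 everywhere for a uniform object, `RadialCV`
  is the CV over eight angular wedges.
- **Shape / Zernike**: area, perimeter, eccentricity, distance-transform
  radii, and the 30 rotation-invariant Zernike magnitudes to degree 9 on
  the centroid-centred unit disc.
- **Texture**: Haralick statistics from symmetrised, normalised GLCMs at
  the four offsets (averaged), 256 grey levels quantised over the object's
  own range, distance 3 px. Entropies use log base 2; sum variance is
  centred on the sum entropy (the original definition). A
  constant-intensity object has zero contrast/entropy and undefined
  correlation.

## Stage classification

Five classes in fixed order — `negative`, `spread`, `disintegrated`,
`netosis`, `dead` (`stageLevels()`) — which is also the tie-break order for
exact probability ties. Training drops all-`NA` and constant columns
(constant columns would otherwise perturb candidate-variable sampling),
freezes training-split medians for imputation, and records a feature-schema
hash that prediction verifies. Cross-validation is stratified per class;
per-class metrics are averaged over folds and confusion matrices summed
then row-normalised. Gini importances are clipped at zero and normalised
to sum to 1.

## Dynamics

- Per-image stage counts become percentages of the image total, are
  IQR-filtered (1.5 × IQR fences, groups under four finite values pass
  with a warning), averaged across fields per well, then summarised as the
  median across wells per treatment.
- TI is the trapezoidal integral of the percentage trace (% · h), computed
  per well and summarised by treatment medians.
- `onset10`/`t50` are interpolated first crossings of 10%/50% of the
  trace's own maximum; the centroid is `sum(t·y)/sum(y)`. These are the
  simplest definitions consistent with the usual "onset", "50% of
  maximum", and "temporal centroid" usage.
- Compositions use the three active stages (spread, disintegrated,
  netosis) with a uniform 0.5 pseudocount before the CLR transform;
  scaling all pseudocounted components by a common factor leaves the CLR
  (and hence the Euclidean distances) unchanged.
- PERMANOVA partitions the squared Euclidean distance matrix; the
  permutation p-value uses the +1 convention
  `p = (1 + #{F* ≥ F}) / (1 + nPerm)`, so the minimum attainable p is
  `1/(nPerm + 1)` and the test is exact-level under exchangeability.
- The contribution of component *i* to a group shift is
  `(ΔCLR_i)² / Σ_j (ΔCLR_j)² × 100`, which sums to 100 by construction.
- Agreement between counting methods: ICC(2,1) (absolute agreement) and
  ICC(3,1) (consistency) from the two-way ANOVA of the n × 2 rating
  matrix, Lin's CCC with n−1 moment estimates, Bland–Altman bias ± 1.96
  SD, Spearman correlation, MAE/RMSE, and the rank-biserial correlation of
  the paired signed ranks (undefined when all differences are zero).

## Synthetic generator

`renderFrame()` renders geometry first (all cell discs and halos), then
fluorescence, so extracellular NET clouds are placed against the *complete*
cell mask and never end up underneath a later cell. Negative cells have
exactly zero fluorescence; every NETosis cell's extracellular cloud is
≥ 150 px. Noise is additive Gaussian read noise plus signal-dependent
Poisson shot noise; `zeroNoise()` disables both. Ground truth (per-cell
stage, cell and NET label masks) accompanies every frame, and
`simulateRun()` writes a fully ingestible on-disk run with logistic
per-stage transition schedules.

## Known limitations

- Cell bodies that physically overlap in the ground truth segment as one
  object unless the declumping scale separates them; the synthetic layout
  accepts this and evaluates NET counts (exact) rather than cell counts
  (bounded between clump and cell counts).
- The granularity spectrum is the plain opening spectrum; values are not
  numerically interchangeable with implementations that subsample and
  reconstruct.
- Mixed-effects inference on TIs is delegated to standard modelling tools
  on the exported tidy tables; no bespoke estimator is bundled.
- The Annexin rim of a dying cell may merge with its neighbour under heavy
  noise; red-channel intensity features on the cell mask still capture
  Annexin positivity in that case.
```{r session}
sessionInfo()
```
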