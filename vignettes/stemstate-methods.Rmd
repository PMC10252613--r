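---
title: "Evaluating MSC differentiation state from label-free microscopy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating MSC differentiation state from label-free microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mesenchymal stem cells (MSCs) induced toward adipogenic or osteogenic
lineages differentiate asynchronously: at any timepoint a culture is a
mixture of undifferentiated, differentiating and differentiated cells.
Population averages of label-free readouts — the protein-bound NAD(P)H
fraction `a2` from fluorescence lifetime imaging (FLIM), or lipid signal
from stimulated Raman scattering (SRS) at 2850 cm⁻¹ — hide this
heterogeneity. `stemstate` implements a single-cell route instead:

1. obtain per-pixel `a2` maps (bi-exponential decay fitting),
2. cut single cells out of dense monolayers with a sliding-window screen,
3. extract per-cell metabolic and morphological features,
4. cluster cells with K-means++ (cluster count from the elbow rule), and
5. read differentiation state off the temporal drift of the clusters.

Because raw microscope data for this kind of study is rarely shareable, the
package ships a synthetic-data generator that renders FLIM and SRS fields
with exact per-cell ground truth; every stage is benchmarked against it.

## Decay model and `a2`

A NAD(P)H fluorescence decay is modelled as
`I(t) ∝ a1·exp(−t/τ1) + a2·exp(−t/τ2)` with `a1 + a2 = 1`, where the short
component `τ1` is free and the long component `τ2` protein-bound NAD(P)H;
`a2` is the protein-bound fraction and the amplitude-weighted mean lifetime
is `τm = a1·τ1 + a2·τ2`. `fit_biexponential()` performs Poisson-weighted
Levenberg–Marquardt least squares on time-binned counts with the
parameterization `(amplitude, a2, τ1, τ2)` — the constraint `a1 = 1 − a2`
is structural, not a post-hoc renormalization. Lifetimes are box-bounded to
standard NAD(P)H ranges (`τ1 ∈ [0.1, 1]` ns, `τ2 ∈ [1, 6]` ns), which also
enforces `τ1 ≤ τ2`. Three starting values of `a2` (0.2, 0.5, 0.8) guard
against local minima; the best converged fit wins.

Choices worth knowing:

* **No instrument response function.** The generator emits ideal decays,
  so no IRF deconvolution is implemented. On real TCSPC data with a
  non-negligible IRF the fitted `τ1` absorbs part of the IRF width.
* **Per-pixel vs global lifetimes.** `build_a2_map()` fits all four
  parameters per pixel by default; `tau_mode = "global"` fixes `(τ1, τ2)`
  and solves a fast non-negative two-amplitude problem per pixel.
* **Minimum photons.** Pixels with fewer than 100 photons are flagged
  background (`a2 = 0`), the usual floor below which a bi-exponential fit
  is not identifiable.
* Recovery under the study conditions (10⁵ photons, 256 bins over 12.5 ns):
  median `|â2 − a2|` is well below 0.01 for `a2 ∈ {0.1 … 0.4}`; the
  acceptance script recomputes this.

## The synthetic generator

`generate_field()` renders elongated adherent cells as ellipses with a
sinusoidal boundary perturbation (5–12 % amplitude, 3–6 lobes) — enough
irregularity to exercise contour tracing while keeping area, perimeter and
eccentricity controllable. Each cell carries a darker, near-circular
nucleus (30 % of the effective radius, offset up to 10 %). Placement is
rejection sampling on centres; a hard floor on centre distance guarantees
nuclei never overlap while `spacing_factor` below ~1.1 lets cytoplasm touch
(the "unclear boundaries" regime). FLIM pixels inside a cell are drawn from
a per-cell Gaussian `N(peak, width)` clipped to [0, 1]; SRS images are
Poisson draws from a rate map (background 10, cytoplasm 150, nucleus 2
counts, plus droplet discs of radius 2–3.5 px). Gaussian read noise
(SD 0.004) models the FLIM background.

State defaults encode the differentiation trend: `a2` peak 0.19 ± 0.02
(undifferentiated), 0.25 ± 0.02 (differentiating), 0.32 ± 0.025
(differentiated) — the undifferentiated and differentiated anchors match
the reported sub-30 % vs above-30 % split and the ~19 % early-adipogenesis
peaks; within-cell `a2` SD 0.035/0.050/0.065; droplet load 1/6/14 per cell;
areas 1500/2100/2700 px² with cells becoming rounder as they mature. The
default time course (Days 1, 7, 14, 21, 28) drifts from 80/10/10 to
5/25/70 percent undiff/differentiating/diff. Day labels and mixtures are
configurable; the defaults are what the tests and the acceptance script
exercise.

What the generator does **not** emulate: optics (no point-spread function,
no vignetting), 3-D structure, cell-to-cell contact biology (touching cells
are independent renders), autofluorescence from non-NAD(P)H sources, and
microscope drift. Passing benchmarks on synthetic fields therefore
demonstrates the pipeline's logic and calibration, not robustness to every
artefact of real acquisitions.

`synth_feature_table()` samples the same per-cell quantities without
rasterizing images — used to benchmark the clustering stage at scale.

## Adaptive threshold

Several stages binarize at the grayscale-histogram peak ("pixels above the
background peak are foreground"). Read literally this rule is unstable:
clipped read noise puts a point mass at zero, so thresholding at the modal
bin leaves a few percent of background pixels above threshold, and the
closing step then aggregates that speckle into nucleus-sized false objects.
The implementation therefore smooths a 256-bin histogram (3-bin moving
average), finds the modal bin, and walks right while the count is either
above 5 % of the peak **or still strictly decreasing** — i.e. the threshold
sits at the right edge of the whole background lobe. For clean backgrounds
this reduces to the plain peak rule; for noisy ones it is the same rule
applied to the background lobe rather than its tallest bin.

## Sliding-window segmentation

Dense MSC monolayers defeat watershed and out-of-the-box learned
segmenters, so single cells are found by screening many overlapping crops:

* **Window sizes** come from measured cell bounding boxes
  (`estimate_window_matrix()`): the 25/50/75/95th percentiles of ~50
  observed sizes, each dimension inflated 20 %, deduplicated, minimum
  32 px. Windows slide at 10 % of their dimension, with the final
  row/column clamped to the border so coverage is complete.
* **Per-crop screen** (`screen_crop()`): binarize → closing (5-px disc) →
  find contours (foreground components *and* interior holes — the dark
  nucleus inside a bright cell is a hole) → sort by area. The largest
  contour is the cell, the second largest the nucleus candidate; the crop
  is accepted iff the candidate's convex-hull circularity reaches
  `c_min = 0.7` **and** its centroid lies within 15 % of the crop diagonal
  from the centre. Both tests must pass, so their order does not change
  the accepted set; the cheap centroid test runs first and contours are
  only traced for centred candidates. Area ties for the nucleus slot go to
  the more circular contour.
* **Duplicates**: every cell is accepted in many overlapping windows.
  Greedy non-maximum suppression keeps the detection with the smallest
  centroid offset and removes any whose nucleus mask overlaps a kept
  nucleus with IoU > 0.3.
* **Prescreen** (on by default, `segment_params(prescreen = FALSE)` to
  disable): a window can only be accepted if an interior hole of the
  field-level closed binary lies within the centroid tolerance of the
  window centre, so windows without a near-centre nucleus are classified
  from an integral image without full screening. On benchmark fields this
  changes throughput (~4×), not detections.

Contours are traced by marching squares (`contourLines` at level 0.5) with
a 3-point circular moving average on the vertices; the smoothed polygon
length is an approximately unbiased perimeter (a digitized disk of radius
50 measures within 2 % of `2πr`, a square keeps circularity ≈ π/4). Area is
always the foreground pixel count; circularity is `4π·area/perimeter²`.

On ten 640×640 fields of 50 non-touching cells (the separability the
benchmark prescribes; at 512² this cell load sits at the packing limit of
rejection-sampling placement), detection recall and precision against
ground-truth nuclei are ≥ 0.96 — recomputed by the acceptance script.

## Features

* FLIM: cell area (px²), `a2` histogram peak, and FWHM of the histogram
  (bin width 0.01 — one percentage point, matching the precision of
  reported peaks; FWHM by linear interpolation of the half-maximum
  crossings around the global modal bin).
* SRS: area, perimeter, circularity, mean gray value (masked sum divided
  by masked pixel count).

The mask (`build_mask()`) follows the histogram-peak threshold → dilation
(5-px kernel) → 3×3 mean filter re-binarized at 0.5 → largest connected
component recipe, then fills interior holes: it is a cell *region* mask,
so the nucleus contributes to area and mean gray. The dilation leaves a
~2-px background margin around the true footprint by construction; the `a2`
histogram ignores masked pixels at or below `a2_floor = 0.02` so that
margin and the dark nucleus cannot form a spurious background mode
(protein-bound fractions of living cells sit far above 2 %).

Features are min–max scaled to [0, 1] before clustering
(`normalize_features()`), with parameters stored so held-out cells can be
projected; constant columns map to 0 with a warning. The normalized table
carries a schema flag; `cluster_cells()` refuses tables without it.

## Clustering and model selection

`kmeanspp_seed()` implements D²-weighted seeding: the first centroid is
uniform over the data, each next one is drawn with probability proportional
to the squared distance to the nearest chosen centroid. `fit_kmeans()` runs
Lloyd iterations (squared Euclidean distance, ties to the lowest index,
empty clusters re-seeded at the farthest point) over 10 restarts and keeps
the lowest within-cluster sum of squares (WCSS). For tiny inputs, where
random restarts can still miss the optimum, Lloyd is additionally seeded
from every distinct k-subset of the points (n ≤ 12 and C(n, k) ≤ 64); under
those conditions the test suite verifies agreement with the
exhaustive-partition optimum on random instances.

**Elbow rule.** The cluster count is the knee of the WCSS curve over
k = 1…8. Two details matter:

* The curve is made non-increasing by construction: each k is also
  warm-started from the best (k−1) solution plus its farthest point.
* The knee is the interior k with the maximum vertical distance below the
  chord joining the curve's endpoints. The more common "maximum second
  difference" rule was evaluated first and rejected: with three states
  ordered along the `a2` axis (exactly the geometry of differentiation
  data) the 1→2 WCSS drop dominates the second difference and the rule
  returns k = 2 systematically. The chord criterion returns k = 3 across
  seeds for both modalities and on symmetric well-separated blobs, and
  k = 3 matches the cluster count this kind of experiment reports.
  When the knee's prominence (chord distance over total WCSS drop) is
  below 0.4 the curve is effectively smooth — a single Gaussian cloud
  lands near 0.31, genuinely clustered data at 0.46+ — and the result
  carries a `flat` flag.

**State mapping.** With k = 3 and at least two timepoints,
`assign_states()` labels the cluster whose occupancy falls most from the
first to the last day `undiff`, the one that rises most `diff`, and the
remainder `differentiating` — the same temporal argument used to interpret
clusters in induction experiments, automated. Ties raise an explicit
ambiguity error rather than a silent guess.

`proportion_table()` reports per-day, per-cluster mean ± SD of per-field
fractions (SD over replicate fields, n−1 denominator, 0 for a single
field); `combined_proportion()` sums chosen clusters per field first — the
differentiating + differentiated sum is the quantity comparable to the
fraction of ALP-stained cells in osteogenic validation.

## Statistics

`ztest_two_means()` and `ztest_two_proportions()` are the classical
large-sample Z-tests (two-sided; pooled proportion for the latter), chosen
because per-timepoint cell counts run in the hundreds. Group sizes below 30
trigger a warning. Zero-variance inputs degrade explicitly (z = 0/p = 1 for
equal means, an infinite-z flag otherwise). Labels: `NS` at p ≥ 0.05 (the
boundary is NS), `*`, `**`, `***` below 0.05/0.01/0.001. No
multiple-testing correction is applied — comparisons are reported pairwise,
as is conventional for this kind of figure annotation — which is a known
limitation when many timepoint pairs are scanned. Whether to compare
per-cell values or per-field means is the caller's choice of inputs;
per-cell is what the pipeline feeds.

## Pipeline and reproducibility

`run_pipeline()` executes synth → segment → features → cluster → stats per
modality from a single `run_config()`. One master seed deterministically
derives every per-stage seed, so identical configurations reproduce every
output — images, CSVs, model JSON and the manifest — bit-identically; the
manifest stores md5 checksums of all outputs and contains no timestamps.
The default configuration (three 512×512 fields of 50 cells per timepoint,
five timepoints, cells allowed to touch) lands 150–200 accepted cells per
timepoint, the input size the clustering stage is designed around; the
pipeline warns if a run leaves that band. Problem sizes throughout (640²
benchmark fields, 10⁵-photon decays, 150 cells × 5 timepoints × 10 seeds
for mixture recovery) were chosen so a full desktop run of the test suite
and acceptance script completes in minutes.

## Numerical corner cases

* Constant image → threshold `Inf` → explicit mask-failure error.
* Decay with all counts in one bin, or fewer than 4 non-empty bins →
  fit-failure error, never silent defaults.
* Delta-distributed `a2` → FWHM equals one bin width (interpolated
  crossings at ± half a bin).
* Half-maximum crossing not reached before the histogram edge → the edge
  is used.
* Empty cluster during Lloyd iteration → re-seeded at the farthest point.
* Equal-area contour tie for the nucleus slot → higher circularity wins.
* `generate_decay()` accepts `τ1 = τ2` (degenerate mono-exponential), and
  rejects `τ1 > τ2`.

## Known limitations

* No IRF handling, phasor analysis, or triple-exponential decays.
* The sliding-window screen assumes nuclei darker than cytoplasm (true for
  NAD(P)H FLIM and lipid-channel SRS); bright-nucleus stains would need an
  inverted screen.
* Touching cells can merge in the feature mask (the largest component
  absorbs the neighbour), inflating area for a small fraction of cells in
  dense fields — the same failure mode manual cropping has.
* The Z-tests are uncorrected pairwise comparisons.
* Synthetic benchmarks bound what can be claimed about real data (see the
  generator section).
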