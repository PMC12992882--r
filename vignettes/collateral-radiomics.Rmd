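---
title: "Collateral scoring from cerebrovascular CTA radiomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collateral scoring from cerebrovascular CTA radiomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collrad)
```

## The problem

In acute ischemic stroke due to large vessel occlusion (LVO), the
*collateral status* — how well pial vessels distal to the occlusion fill
via alternative routes — predicts infarct growth and informs thrombectomy
decisions. On CT angiography (CTA) it is commonly graded with the 4-point
Tan score by comparing opacified vessels distal to the occlusion against
the contralateral hemisphere (0: no filling; 1: up to 50%; 2: more than
50% but incomplete; 3: complete). Manual grading is rater-dependent;
`collrad` implements an automated alternative: radiomics computed over
vessel-derived regions of interest feed a random-forest classifier of
*sufficient* (Tan 2–3) versus *non-sufficient* (Tan 0–1) collaterals.

The pipeline assumes template-space inputs: a brain-extracted CTA, a
binary vessel-tree mask, a multilabel circle-of-Willis (CoW) mask, and an
MCA arterial-territory atlas, all co-registered on one grid. Brain
extraction and rigid template registration are upstream prerequisites
(e.g. SynthStrip and FLIRT) and are deliberately not reimplemented here.

## The synthetic phantom

Clinical CTA with collateral annotations is not freely available, so the
package ships a generator of synthetic cases that carries exactly the
statistical structure the classifier exploits: collateral sufficiency
expressed as distal vessel filling relative to the mirrored contralateral
side.

Each case is a two-hemisphere tubular vessel tree on a 96×96×96 grid at
1 mm isotropic spacing (large enough for mesh-based shape features, small
enough for desk-scale experiments). Internal carotid segments rise to a
CoW-like ring (labeled MCA-L/R, ICA-L/R, ACA, PCA, Acom, Pcom, BA); an M1
gap simulates the occlusion on a randomly drawn side; beyond the gap a
recursive bifurcating tree (default depth 4) fills the hemisphere. The
baseline geometry is mirror-symmetric with per-case jitter applied
identically to both sides, so the contralateral hemisphere is a valid
reference — mirroring operates on rasterized voxel index sets, which makes
the symmetry voxel-exact rather than approximate. Every distal voxel on
the occluded side is retained with probability `fill_fraction`; the Tan
analog is 0 for no filling, 1 for fill ≤ 0.5, 2 for incomplete fill above
0.5, and 3 for complete filling. Cohorts are stratified exactly:
`round(n_cases * p_insufficient)` cases are non-sufficient (the default
0.33 matches typical LVO cohort proportions).

Intensities are plausible rather than scanner-calibrated: tissue 35 ± 5 HU
inside a brain ellipsoid, contrast-filled vessels 250 ± 50 HU, additive
Gaussian noise of 10 HU. Fill fractions are drawn uniformly within the
class ranges, with point masses at the endpoints (probability 0.25 at
complete filling when the range allows it, 0.15 at zero filling) so that
all four Tan grades occur; the proportions echo the clinical rarity of
Tan 0 relative to Tan 1.

What the phantom does *not* emulate — and what passing tests therefore do
not show about clinical data: anatomically faithful vasculature and its
variants (fetal PCA, hypoplastic A1, ...), beam hardening, motion,
multi-phase acquisition timing, and segmentation errors from upstream
models. The phantom validates the *pipeline*, not the clinical claim.

## Preprocessing and ROI construction

CTA intensities are clipped to the 1–500 HU window (inclusive; values
below 1 HU are set to 1) and z-scored per scan using the moments of the
clipped volume. The normalization support is the whole loaded volume by
default; since inputs are brain-extracted, this equals the brain support.
Whether the z-scoring should precede or follow brain masking is not
determined by the upstream description; the whole-volume choice is fixed
here and flagged for sensitivity analysis. A constant scan raises an
error rather than silently producing zeros.

Volumes are reoriented on load so that the first array axis runs
patient-left to patient-right ("RAS"), which makes hemisphere splitting a
plane cut at the first-axis midpoint: voxels with index at or below half
the (even) extent go left, the rest right — an exact partition, with
midline-straddling vessels such as the basilar artery attributed by the
same rule. Three ROI schemes are supported:

* **A (vessel shape)** — the two hemispheric vessel-tree masks;
* **B (territory texture)** — per-side composite MCA territories, built
  from the atlas by keeping only MCA subregions and merging them;
* **C (seven ROIs)** — both hemispheric trees, per-side ICA and MCA from
  the merged CoW mask, and one merged communicating-vessel class (ACA,
  PCA, Acom, Pcom, BA pooled), i.e. the 5-label CoW scheme.

Non-canonical atlas label names are accepted through a plain-text alias
table (`A3 = ACA` and similar).

## Radiomics

Variants A and C use the 14-feature 3D shape set computed from a
triangulated isosurface of each mask: mesh volume, voxel volume, surface
area, surface-to-volume ratio, sphericity, maximum 3D diameter, three
in-plane maximum diameters, three eigenvalue-derived axis lengths,
elongation and flatness. The isosurface is a marching-cubes style mesh at
iso-level 0.5 with vertices at voxel-edge midpoints; the
per-configuration triangle table is derived programmatically by
marching-squares contouring of the cube faces and stitching the oriented
segments into closed loops (ambiguous faces always keep the
inside-corners separated, a rule local to the face, so adjacent cubes
agree and the mesh is watertight). Loops longer than three vertices are
fanned from their centroid. The centroid fan makes surface area and
enclosed volume *exactly* invariant under the cube symmetry group — the
package's geometric-invariance tests demand 1e-9 relative agreement under
90° rotations — at the price of a small systematic triangulation
difference from classic Lorensen marching cubes (up to roughly 2–3% on
surface-derived quantities for thin, jagged masks; about 1.8% on the
sphericity of a radius-15 digital ball). The cross-check test against an
independent reference implementation therefore compares SurfaceArea,
MeshVolume, SurfaceVolumeRatio and Sphericity at 3% and every other
feature at 1%.

Variant B extracts 18 first-order and 38 texture features (22 GLCM + 16
GLRLM) per ROI from 12 images: the original normalized volume, the 8
sub-bands of a one-level stationary coif-1 wavelet decomposition, and
Laplacian-of-Gaussian responses at σ ∈ {1, 2, 3} mm — 56 features × 12
images × 2 ROIs = 1344 columns. Choices fixed by the package where the
protocol is underdetermined:

* **Discretization**: fixed bin count B = 32, left-closed equal-width bins
  over the ROI min–max with the maximum in the top bin. A fixed *count*
  (not width) is robust on z-scored intensities, whose scale is already
  per-scan normalized.
* **GLCM**: distance 1 voxel, symmetric, normalized per direction, 13
  unique 3D directions aggregated by mean. The 22-feature set is the
  standardized GLCM family without MCC and without SumAverage (which
  equals twice JointAverage under symmetry).
* **Wavelet**: one decomposition level, stationary (undecimated) with
  periodic boundary, so every sub-band stays on the input grid and the
  original masks apply unchanged; band names follow the axis order of
  filter application.
* **LoG**: separable implementation with σ interpreted in mm through the
  voxel spacing, kernels truncated at 4σ and moment-corrected (the
  smoothing kernel sums to one, the second-derivative kernel to zero, so
  constants map to zero exactly), scale-normalized by σ². The default
  sigmas span vessel calibers at 1 mm spacing.

Feature columns are named `{roi}|{filter}|{class}|{feature}` and are
bit-stable across runs, which makes selection results diffable.

## Feature selection

All selection statistics are computed on the training rows only. The
stages are:

1. **Min–max scaling** fitted on the training rows; test rows are mapped
   through the training parameters and deliberately left unclipped, so a
   test value outside the training range lands outside [0, 1] rather than
   leaking its existence into the scaler.
2. **Importance**: an L2-regularized logistic regression (inverse
   regularization C = 1, a fixed default whose sensitivity is covered by a
   test sweep rather than hidden tuning) is fitted on the training part of
   each of 10 stratified CV folds; a feature's importance is its mean
   absolute coefficient across folds. The classification model follows
   the task; a ridge *regression* would ignore the binary outcome's
   geometry.
3. **Correlation pruning**: from every training-set feature pair with
   Pearson |r| strictly above 0.9 the less important member is dropped.
   Pairs are processed in descending |r| then lexicographic name, and an
   importance tie discards the lexicographically later name — the result
   is deterministic and invariant to column order. Pearson correlation
   matches the "r > 0.9" idiom; constant columns, whose correlation is
   undefined, are retained with a warning.
4. **Incremental search**: nested subsets top-5, top-6, …, top-K of the
   pruned ranking are scored by mean 10-fold stratified CV AUROC of the
   same ridge logistic model (same folds for every k, so the trace is
   comparable across k); the arg-max subset wins and AUROC ties resolve
   to the smallest k. Fewer than five candidates trigger a single
   evaluation with all of them.

A permutation guard verifies the machinery cannot manufacture signal:
running the full selection-and-training pipeline on label-permuted
cohorts yields held-out AUROC with median inside [0.4, 0.6].

## Classifier

The final model is a 1000-tree probability random forest on the selected
features, validated with stratified 4-fold CV on the training rows.
Hyperparameters — depth bound (3–20 or unlimited), minimum node size
(1–10), feature-subsample fraction (0.2–1), class weighting (none or
balanced) — are tuned by a sequential model-based optimizer in the
tree-structured-Parzen style: 10 random startup trials, then candidates
sampled from a kernel density over the best quartile of past trials and
ranked by the good/bad density ratio, with exactly 50 objective
evaluations by default. The tuning objective is mean stratified 5-fold CV
AUROC of a 300-tree forest; only the final fit uses 1000 trees — an
efficiency split, since the ranking of hyperparameters stabilizes well
below the final ensemble size. Every stage is seeded deterministically
from one master seed, and the whole train-predict path is bit-stable: a
rerun under the same configuration produces byte-identical selection JSON
and model archives. Predictions are dichotomized at probability 0.5.

## Evaluation

AUROC is the Mann–Whitney pair statistic (ties one half) computed from
midranks. Confusion-matrix rates treat *sufficient* as the positive class
and report zero-denominator rates as undefined rather than zero;
reported values are rounded half-up to three decimals. Confidence
intervals are stratified percentile bootstraps (B = 2000), chosen for
being assumption-light. Paired model comparison uses the DeLong
structural-components estimator in its midrank O(n log n) form, verified
in the tests against a brute-force O(n²) double loop; comparing a model
with itself returns z = 0, p = 1 by convention, and differences are
called significant at p < 0.05. Shipped feature attribution is
permutation importance (mean AUROC drop over 20 shuffles per feature);
an exact-Shapley enumeration serves as a test oracle on small forests
but is not the shipped method, since exact tree-path attribution is heavy
engineering orthogonal to the classifier itself.

## Problem sizes in the test suite

The validation suite runs at desk scale, chosen so the full suite
completes comfortably on one CPU: the end-to-end recovery experiment uses
210 phantom cases (150 train / 60 test) at the default 96³ grid with
strongly separated fill ranges ([0.7, 1] versus [0.1, 0.4]) and the full
50-trial tuning budget; the permutation-null guard reuses the same
extracted features over 10 label permutations with a reduced 6-trial
tuning budget (the null distribution of a forest's held-out AUROC does
not depend on how carefully its hyperparameters were tuned); selection
correctness uses synthetic tables with 5 planted signal features among 45
noise features at effect size d = 2, n = 300, over 5 seeds. Unit tests
use 48³ phantoms with shallower trees.

## Known limitations

* The seven-ROI and vessel-shape models share their hemispheric ROIs by
  construction; on the phantom, most class signal lives there, so the two
  variants perform similarly — clinical differences between them cannot
  be reproduced synthetically.
* The binary midline split misattributes vessels that cross the plane;
  this mirrors the upstream method's own limitation and is documented
  rather than corrected.
* Texture features on the phantom mostly reflect vessel density inside
  the territory masks, not genuine parenchymal texture.
* The marching-cubes triangulation convention (centroid fan) trades a
  small systematic surface-area offset for exact rotational symmetry; see
  the radiomics section.
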