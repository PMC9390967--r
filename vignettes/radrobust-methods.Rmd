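---
title: "Robustness-aware radiomics modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robustness-aware radiomics modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radrobust)
```

## The problem

Quantitative CT texture descriptors ("radiomics") are candidate biomarkers
for predicting whether an advanced NSCLC patient will respond to anti-PD-1
therapy — but they are notoriously fragile: reconstruction settings,
patient positioning and contouring variability all move feature values.
`radrobust` implements a complete, testable version of the
robustness-aware modelling recipe for that setting:

1. simulate (or load) a cohort of lesion images with binary response
   labels;
2. normalize images and select the three-slice analysis slab;
3. apply three perturbation families emulating multicentre variability —
   slice thickness **S** (1/2/3/5 mm reconstructions), in-plane rotation
   **R** (±15°, ±30° about the lesion centroid) and contour variation
   **Seg** (±2 mm morphological dilation/erosion of the ROI);
4. keep only features whose ICC(2,1) across every family exceeds 0.75
   (strict), drop zero-MAD columns, and z-score with train statistics;
5. search an extractor × selector × classifier grid (7 × 13 × 12 = 1,092
   models) under stratified cross-validation with SMOTE rebalancing, and
   pick the model with the highest mean AUC, ties broken by the lowest
   relative standard deviation RSD = 100·sd(AUC)/mean(AUC).

Real patient CTs are not required anywhere: the synthetic cohort generator
is a first-class, tested module, and every downstream stage is exercised
against it.

## The synthetic world

`generate_lesion()` builds an ellipsoidal lesion in a homogeneous
lung-like background (−800 HU). In-lesion intensity is
`mean_hu + GRF + noise`, where the Gaussian random field (GRF) is white
noise convolved with a Gaussian kernel of FWHM `texture_corr_mm`,
renormalized so its marginal SD is exactly `texture_sd_hu`; acquisition
("quantum") noise is i.i.d. Gaussian everywhere. The two cohort classes
differ in texture correlation length (default 4.5 mm responsive vs 1.5 mm
unresponsive) — a deliberately recoverable, purely textural effect.

Choices that were genuinely open, and why they were fixed as they are:

* **Peritumoral rim.** Intensities do not step from tumour to −800 HU at
  the contour: they stay tumour-like for `rim_mm` (3 mm) beyond the
  ellipsoid surface and then decay to background over `rim_decay_mm`
  (3 mm, raised cosine). Without the rim, a 2 mm ROI dilation pulls in
  pure air, every intensity feature collapses under the Seg family, and
  the qualitative behaviour reported for clinical lung cohorts (intensity
  features largely robust to contouring variation) cannot be reproduced. The rim models infiltrative margins, partial-volume and
  respiratory blur; the binary mask itself is unchanged.
* **Between-subject heterogeneity.** Per-subject lognormal jitter on the
  semi-axes (SD 0.35 — lesion volumes span about a decade, as
  RECIST-measurable target-lesion cohorts do), additive jitter on the mean
  intensity (SD 40 HU — variable enhancement) and lognormal jitter on
  texture amplitude (SD 0.3). ICC is a variance ratio: with near-identical
  subjects, no feature is "robust" no matter how stable it is, so a
  generator without realistic heterogeneity cannot emulate published ICC
  distributions. With these defaults roughly 30 % of the 107 original
  features pass the 0.75 gate, close to published retention fractions for
  this pipeline family.
* **Baseline slice thickness 3 mm** (in-plane 0.75 mm), the midpoint of
  the emulated 1–5 mm protocol, so the S family resamples both finer and
  coarser.
* **Seeding.** Everything flows from one cohort seed through
  `derive_subseed()` (Lehmer-style mixing, always < 2³¹); a subject's
  texture field and its acquisition noise use separate sub-streams so that
  test–retest replicates can re-realize the same lesion with fresh noise
  and a ≤ 1 voxel rigid repositioning shift.

What a green test on this world does **not** establish: absolute feature
values on real CTs, vendor/kernel effects, breathing artifacts, lesions
attached to mediastinum or chest wall, or the discriminative value of any
specific feature in patients. The world is a statistical emulator for
pipeline behaviour, not a CT simulator.

## Preprocessing

Fixed order: window/level → (optional) histogram equalization → Gaussian
denoising → maximum-area slab selection, with ties on the slab sum broken
toward the smallest starting slice.

* **Windowing** defaults to the fixed lung window (centre −600, width
  1500 HU) followed by affine rescaling to [0, 1]. The adaptive mode
  (centre = ROI mean, width = 6 × ROI SD; zero-variance ROIs fall back to
  the fixed window with a warning) is available, but it re-derives the
  intensity mapping from each — possibly perturbed — ROI, which erases the
  absolute intensity scale whose agreement ICC(2,1) measures; using it
  inside the robustness loop makes intensity-feature ICCs noise-dominated.
* **Histogram equalization** is implemented (classic CDF mapping, monotone)
  but off by default on the radiomics path: global equalization maps the
  in-ROI intensities onto the lesion's volume fraction of the CDF (a few
  per cent of the range), so the default 25-wide discretization bins
  collapse to one or two gray levels and all texture matrices degenerate.
  It exists for display and CNN-style inputs.
* **Denoising** uses a separable Gaussian (default sigma 0.75 mm = one
  in-plane voxel) with half-sample-symmetric boundaries, which conserve
  the global mean exactly for symmetric kernels.
* **Resampling** interpolates the image linearly. The mask uses
  nearest-neighbour when upsampling and box occupancy (≥ 50 %) when
  downsampling: plain NN on a coarse grid quantizes the lesion by whole
  slices, changing its volume far more than thick-slice partial-volume
  reconstruction does.

## Feature extraction

107 original features — 14 shape, 18 first-order, 24 GLCM, 16 GLRLM,
16 GLSZM, 14 GLDM, 5 NGTDM — plus the 93 non-shape features on each of
8 stationary-wavelet sub-bands: 851 in total, named
`<filter>_<class>_<name>`.

Numerical conventions (all covered by tests against an independent
reference implementation on three frozen fixture lesions):

* Discretization: fixed bin width (default 25 on the 0–255 display-scaled
  slab), levels `floor((v − min)/w) + 1` from the in-mask minimum,
  re-derived per image filter.
* GLCM and GLRLM are built per direction over the 13 unique 3-D distance-1
  directions; each direction's matrix is normalized and scored separately
  and feature values are averaged over non-empty directions. GLSZM uses
  26-connected equal-level zones; GLDM dependence = 1 + the number of
  26-neighbours with an equal level (α = 0); NGTDM uses the
  26-neighbourhood mean of in-mask neighbours.
* Degenerate conventions, chosen so no feature is ever missing: GLCM
  correlation = 1 and MCC = 1 on a flat matrix; inverse variance sums
  off-diagonal terms only; NGTDM coarseness returns 10⁶ when `Σ p·s = 0`;
  busyness/strength return 0 on zero denominators; skewness/kurtosis of a
  zero-variance ROI are 0. 0/0 situations resolve to 0 unless noted.
* Shape: the mesh is a marching-tetrahedra iso-surface (6 tetrahedra per
  cell around the main diagonal, vertices at voxel-edge midpoints). The
  enclosed volume per tetrahedron is exact for midpoint cuts
  ({0, ⅛, ½, ⅞, 1} of the tetrahedron volume). Midpoint meshes are
  rougher than a smooth ellipsoid, so absolute surface areas run ~25 %
  high and sphericity correspondingly low — consistent across samples and
  identically defined in the reference implementation, but not comparable
  with marching-cubes numbers from other toolkits. Maximum diameters use
  boundary-voxel centres; axis lengths are `4·sqrt(λ)` from the sample
  covariance of physical voxel-centre coordinates.
* Wavelets: one-level *stationary* (undecimated) coif1 transform with
  circular boundaries, so sub-bands stay aligned with the mask; sub-band
  letters are x, y, z order (`LLH` = low-pass in x and y, high-pass in z).
  Texture matrices are re-discretized per sub-band.

The seven extractor slots of the model grid are radiomics variants
(different discretization, wavelet use, preprocessing); the grid
arithmetic is slot-count-agnostic, and CNN extractors can be plugged in as
additional named feature tables.

## Robustness scoring

ICC(2,1) — two-way random effects, absolute agreement, single measurement:
`(MSR − MSE) / (MSR + (k−1)·MSE + (k/n)·(MSC − MSE))`. Each family is
scored separately (baseline + that family's versions as the k columns) and
a feature must exceed the threshold in *every* family (strict `>`, default
0.75); pooling across families by mean is available as a config
alternative because the grouping is a genuinely open choice. A
zero-total-variance matrix is an error at the single-feature level and an
`NA` (never retained) in cohort reports. Zero-MAD columns are dropped as
nonpredictive. Standardization uses the population-SD convention and is
fit inside training folds during CV; a global mode exists for fidelity
runs but leaks test-fold statistics by construction.

## Selection and the model grid

The univariate scorers (CHSQ, ReliefF, Fisher, Gini, Welch-t) and greedy
information-theoretic criteria (MIM, MIFS β = 1, MRMR, JMI, CMIM, CIFE,
ICAP, DISR) share a plug-in MI estimator on 5-bin equal-frequency
discretized features; all ties break by feature-name order. The
recursive-feature-addition wrapper walks a ranking and keeps a feature iff
it improves mean CV AUC by more than 1e-4, capped at 20 features.

Inside each training fold, in order: standardize → select features →
SMOTE (k = 5, to exact balance) → fit. SMOTE after selection is the
default so synthetic points cannot influence selection statistics; the
pre-selection ordering is a config switch. Test folds are never touched by
any fitted statistic. AUC is the Mann–Whitney statistic (ties count ½);
fold AUCs give mean, SD, and RSD; the best row maximizes mean AUC with RSD
and then name as tie-breaks. Confusion metrics for the best model come
from pooled out-of-fold scores thresholded at their median (the cohort's
class ratio is not assumed known at prediction time).

The twelve classifiers follow the common library defaults (k-NN k = 5;
SVMs squared-hinge C = 1, RBF γ = 1/(p·Var); gradient boosting 100 ×
depth-3 trees, learning rate 0.1; MLP one hidden layer of 100, BFGS;
GP = RBF-kernel regression on ±1 labels with noise 0.1; random forest 100
random-subspace trees; AdaBoost 50 SAMME stumps; QDA with pooled- and
diagonal-covariance fallbacks for deficient folds). Because the target
environment provides no tree/SVM/NN packages, these are implemented
in-package (CART in C++); they are contract-compatible stand-ins, not
re-implementations of any specific library's numerics, and their
hyperparameters are echoed into the run manifest.

## Known limitations

* Slice-spacing perturbation is resampling, not raw-data reconstruction.
* The mesh convention (marching tetrahedra) biases absolute surface-area
  and sphericity values relative to marching-cubes toolkits.
* The null calibration of the grid (best permuted-label AUC ≈ 0.5) holds
  at the fold level; model *selection* across 1,092 rows still sees the
  same folds, so reported best-row AUCs carry the usual winner's-curse
  optimism of this study design.
* The GP and SVM classifiers return decision scores, not calibrated
  probabilities; AUC-based selection is rank-invariant to this.

## A minimal run

```{r example, eval = FALSE}
cohort <- generate_cohort(cohort_spec(n_responsive = 20, n_unresponsive = 10))
tab <- remove_zero_mad(extract_cohort(cohort, extraction_config(wavelet = FALSE)))
res <- cohort_perturbation_icc(cohort)
keep <- filter_robust(res$reports)
rows <- run_grid(list(radiomics = tab[, intersect(colnames(tab), keep)]),
                 attr(tab, "labels"), cv = cv_config(k = 5, seed = 1))
select_best(rows)
```

The `rad_cli()` entry point (`simulate`, `extract`, `robustness`, `grid`,
`report`, `all`) chains the same stages from a YAML config and records
every artifact with an MD5 hash in `manifest.json`.
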