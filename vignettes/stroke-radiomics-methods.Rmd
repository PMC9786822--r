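---
title: "Methods: radiomics prognosis for follow-up stroke MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomics prognosis for follow-up stroke MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After an acute ischemic stroke treated by thrombolysis and/or endovascular
thrombectomy, a large fraction of patients remain functionally dependent at
90 days (modified Rankin Scale, mRS, 3–6) even when reperfusion succeeds.
Follow-up MRI at ~24 h routinely includes DWI and T2-FLAIR, on which the
infarct lesion is segmented. The question this package operationalises:
**do quantitative texture/shape/intensity descriptors of the follow-up
lesion add prognostic value for the binary 90-day outcome (mRS 0–2 vs 3–6)
on top of routinely collected clinical covariates?**

The pipeline: lesion radiomics per modality → five feature sets (DWI,
FLAIR, imaging = both, clinical, combination = all) → gradient-boosted tree
classifier per set under nested stratified 5-fold cross-validation with
grid search and SHAP-based feature selection → pairwise DeLong comparison
of the resulting ROC curves → SHAP summary of the best model. Because the
underlying trial data are not public, a synthetic-cohort module generates
inputs carrying the statistical structure the analysis assumes, so every
stage is testable offline.

## Preprocessing

**Resampling.** Volumes are resampled to isotropic 1 mm (trilinear for
intensities, nearest-neighbour for masks, so masks stay strictly binary).
The output grid has `round(size * spacing / target)` voxels per axis, voxel
centres corner-aligned with the input grid; this convention is pinned for
reproducibility.

**White-stripe normalisation.** The highest mode `mu` of the smoothed
within-brain intensity density is located; the "stripe" is the set of
voxels whose empirical CDF value is within `tau = 0.05` of `F(mu)` (a band
holding ~10% of the probability mass around the dominant tissue mode); the
whole volume is z-scored by the stripe mean and SD. Two consequences worth
stating explicitly:

* The procedure is invariant under positive affine intensity maps and
  idempotent up to numerical tolerance (both tested).
* Because the stripe is a *narrow* band, its SD is much smaller than the
  full tissue SD (for a Gaussian, the central 10% band has SD ≈ 0.073 of
  the population SD), so normalised intensities span tens of units. The
  fixed discretisation bin width of 25 (below) therefore yields a usable
  number of gray levels; this interplay is deliberate.

The same mode-based variant is used for both modalities; with no brain mask
supplied the whole field of view defines the histogram.

## Radiomic features (107 per modality)

18 first-order + 14 3D shape + 24 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM +
14 GLDM = 107, all computed from scratch and locked against brute-force
enumeration oracles in the test suite. Conventions that had to be pinned:

* **Discretisation**: fixed bin width 25 on the normalised intensities,
  `level(x) = floor((x − min)/25) + 1`.
* **Texture aggregation**: Chebyshev distance 1, the 13 unique 3D
  directions, per-direction features averaged (GLCM symmetrised and
  normalised per direction); directions without a valid voxel pair are
  excluded. GLSZM zones and all connectivity use 26-connectivity.
* **GLDM**: a neighbour is dependent when its level differs by at most
  `alpha = 0` from the centre; the dependence *size* counts the centre
  voxel, so the matrix entries sum to the number of in-mask voxels. On a
  uniform block the dependence-non-uniformity-normalised (DNN) statistic is
  non-monotone in block size (1 for a 2-cube, 0.336 for a 3-cube, 0.320
  for a 5-cube, rising back towards 1 as the interior dominates) — the
  meaningful monotonicity, which the tests assert, is DNN increasing with
  *texture heterogeneity* at fixed resolution.
* **NGTDM**: neighbourhood means are taken over in-mask 26-neighbours;
  voxels with no in-mask neighbour are excluded.
* **Degenerate fallbacks** (total functions everywhere): constant ROI gives
  Entropy 0, Uniformity 1, Skewness/Kurtosis 0, GLCM Correlation 1, NGTDM
  Strength/Busyness/Contrast 0 and Coarseness capped at 1e6.
* **Shape**: surface area and mesh volume come from a triangulated
  iso-surface of the mask indicator at level 0.5, extracted by marching
  tetrahedra (six tetrahedra per grid cube; the field is linear within each,
  so cut triangles and clipped volumes are exact). The indicator is first
  Gaussian-smoothed with sigma 0.8 voxels: iso-surfacing the raw binary
  field overestimates a sphere's area by ~9% (staircase effect, digital-ball
  sphericity ≈ 0.91), while the anti-aliased mesh is accurate to ~2%
  (sphericity 0.987 for a 10 mm digital ball) at the cost of shrinking
  sub-voxel detail on very small lesions. Single-voxel masks fall back to
  the voxel-cube boundary. Maximum 2D diameters are computed per plane
  (slice/coronal/sagittal) over boundary-voxel centres; axis lengths are
  `4 * sqrt(eigenvalue)` of the voxel-coordinate covariance.

## Classifier and tuning

The classifier is a gradient-boosted tree ensemble (XGBoost backend,
logistic objective, fixed `base_score = 0.5`, single-threaded, seeded)
chosen for its native handling of missing values —
no imputation anywhere; missing values follow each split's stored default
direction. The fitted booster is parsed into an explicit tree table
(feature, float32 threshold, yes/no/missing children, leaf values, covers)
and *all* downstream prediction and attribution walks that representation
independently; tests assert the walked margins reproduce the library's to
float precision (thresholds are rounded back to float32, because the
backend compares in single precision — double-precision comparison
misroutes ties).

Grid search maximises mean inner-fold validation accuracy at threshold 0.5,
ties broken by first-in-grid order. The experimental design names seven
tunable parameters; a 3–4 point grid over all seven is combinatorially
infeasible inside a nested CV (3^7 points × 25 inner fits each), so the
shipped default varies the two most influential — `max_depth` ∈ {2, 3, 4}
and `learning_rate` ∈ {0.1, 0.3} — and holds `min_child_weight = 1`,
`colsample_bytree/bynode = 1`, `subsample = 1`, `alpha = 0`, 50 boosting
rounds with no early stopping (fixed rounds keep runs reproducible). Any
user-supplied grid over all seven parameters is accepted.

## Attribution and feature selection

TreeSHAP (the exact path-dependent polynomial algorithm, cover-weighted
conditional expectations as the value function) is implemented in C++ and
verified three ways: against a brute-force Shapley oracle that enumerates
all 2^d feature subsets (d ≤ 12), against the backend's own attribution on
random models, and via the local-accuracy identity
`base + sum(phi) = margin` on every attribution. Positive attributions push
towards the unfavourable class pipeline-wide.

Inside each outer fold, with the tuned hyperparameters, models are fit on
each inner-training split and SHAP values computed on the corresponding
inner validation fold; mean |SHAP| per feature is averaged across folds and
features at exactly zero (≤ 1e-12, absorbing float noise) are discarded —
the null-player property guarantees features never split on get exactly
zero. The model is then refit on the full outer-training set with the kept
features and scored on the untouched outer test fold. Test-set SHAP values
are pooled for the beeswarm-style export.

## Evaluation

Accuracy, sensitivity, specificity, precision (positive class =
unfavourable; precision falls back to 0 with no positive prediction;
threshold 0.5 — the design leaves the threshold unstated) and midrank
Mann–Whitney AUC are computed per outer fold; Table-1-style summaries
report the mean with a 95% t-interval over the five outer folds (the CI
construction is likewise unstated upstream; the t-interval is this
package's choice).

DeLong's test compares correlated AUCs using the fast midrank placement
formulation; it is applied to the pooled out-of-fold score vectors, one
paired comparison per model pair on identical samples (pooling vs per-fold
is another pinned choice). Zero variance with zero AUC difference returns
p = 1 by convention. The implementation is locked against a direct
all-pairs placement-matrix oracle (agreement to 1e-10) and cross-checked
against an independent R implementation; a 500-replicate null simulation
keeps the rejection rate at alpha = 0.05 inside [0.02, 0.09].

## The synthetic cohort

What it emulates — the structure the analysis needs, at the stated study
conditions:

* **Lesions**: unions of 1–3 randomly perturbed ellipsoids, smoothed and
  thresholded, largest 26-connected component kept; mean radii 4–10 mm on a
  40×40×22 grid at 1.5×1.5×3 mm (thick-slice acquisition, exercising the
  resampling stage). With irregularity 0 the mask is exactly the digital
  ball, which anchors the shape tests.
* **Texture**: inside the mask, a Gaussian random field standardised and
  scaled to SD `15 + 135 h` (arbitrary MR units against a background of
  mean 100, SD 10; lesions hyperintense at mean 300/250 for DWI/FLAIR),
  with smoothing kernel SD `2.2 − 1.8 h` voxels. One scalar `h` in [0, 1]
  thus raises variance and spatial roughness together; through the full
  pipeline the GLDM DNN feature rank-correlates with `h` at ~0.95. At
  `h = 0` the within-mask variance stays below the documented threshold of
  20².
* **Clinical table**: 23 covariates — the eight named in the study design
  (age, sex, glucose, ASPECTS, treatment arm, pre-stroke mRS, baseline and
  24-h NIHSS) with realistic stroke-cohort distributions, plus fifteen
  generic comorbidity/physiology/workflow stand-ins (the full trial list is
  not public); missingness is completely at random at rate 0.03 by default.
* **Outcome**: `P(mRS 3–6) = logistic(b0 + 1.2 z_h + 0.8 z_vol + 0.8 z_age
  + 1.2 z_nihss)` on internally standardised covariates; the betas were
  chosen once so that imaging (heterogeneity + volume) and clinical (age +
  24-h NIHSS) each carry real but partial signal, the combined model has
  headroom over either alone, and prevalence sits near 0.5 at `b0 = 0`.
  The mRS value is drawn uniformly within the 3–6 or 0–2 stratum — only
  the binary endpoint is modelled.

What it does not emulate — and hence what passing tests do *not* show about
real data: no brain anatomy or skull (so skull-stripping and registration
are out of scope by construction), no hemorrhage or multi-class outcome
structure, no scanner/site effects, no informative missingness, and
modality volumes that differ only in seed and mean intensity rather than in
biology. Recovery results on this cohort demonstrate that the pipeline's
machinery is sound, not that any particular AUC is attainable clinically.

## Problem sizes

The test suite exercises oracles on ≥ 20 random ROIs up to 8³ per texture
family, 50 random models for the Shapley oracle, and n ≤ 30 for the DeLong
oracle. The recovery experiment uses a 200-patient cohort, all five feature
sets, 5×5 nested CV with the default 6-point grid; the null-calibration
simulation uses 500 replicates at n = 60. These sizes are the package's
reference experiment; `scripts/acceptance.R` re-runs them from scratch.

## Known limitations

* Feature values follow this package's pinned conventions; other radiomics
  implementations differ in discretisation, aggregation and mesh details,
  so absolute feature values are comparable only within-pipeline.
* The anti-aliased mesh biases area/volume low for lesions only a few
  voxels across.
* Grid search optimises accuracy (as designed upstream), which is a coarse
  criterion at these sample sizes; the small default grid reflects desk-
  scale compute.
* DeLong on pooled out-of-fold scores treats fold-to-fold model variation
  as part of the score-generating process.
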