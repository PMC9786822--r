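# strokeradiomics

Radiomics-based prognosis modelling for follow-up MRI in acute ischemic
stroke, as a tested, fully offline-reproducible R package.

After reperfusion treatment for large-vessel-occlusion stroke, follow-up
MRI at ~24 h (DWI and T2-FLAIR) shows the infarct lesion; the clinical
question is whether quantitative descriptors of that lesion improve
prediction of 90-day functional outcome — the modified Rankin Scale
dichotomised as mRS 0–2 (independent) vs 3–6 (poor outcome) — beyond
routine clinical covariates. The package implements the whole analysis:

* **Radiomics**, from scratch: 107 features per modality — 18 first-order,
  14 3D shape (mesh volume *V*, surface area *A*, sphericity
  (36&pi;*V*²)^⅓ / *A*, diameters, principal axes) and the five texture
  families GLCM, GLRLM, GLSZM, NGTDM, GLDM at Chebyshev distance 1 over the
  13 unique 3D directions. Every texture matrix is locked against a
  brute-force enumeration oracle in the tests.
* **Preprocessing**: isotropic 1 mm resampling and white-stripe intensity
  normalisation (z-scoring against the ±5% CDF band around the dominant
  histogram mode).
* **Modelling**: gradient-boosted tree ensembles (XGBoost backend, native
  missing-value routing, no imputation) on five feature sets — DWI (107),
  FLAIR (107), imaging (214), clinical (23), combination (237) — under
  nested stratified 5-fold cross-validation: inner grid search maximising
  validation accuracy, then SHAP-based selection discarding features with
  mean |SHAP| = 0 on the inner validation folds, then refit and scoring on
  the outer test fold.
* **Attribution**: exact path-dependent TreeSHAP (cover-weighted
  conditional expectations, C++ kernel), verified against exhaustive
  2^d-subset Shapley enumeration and satisfying local accuracy
  base + &Sigma;&phi; = margin on every sample.
* **Comparison**: DeLong's test for paired correlated AUCs via midrank
  placements, z = (AUC&#8320; − AUC&#8321;) / √var(diff), on the pooled
  out-of-fold scores.
* **Synthetic cohort**: the trial data behind the analysis are not public,
  so a seeded generator produces lesion masks (perturbed ellipsoids),
  within-lesion texture with a controllable heterogeneity level *h*,
  a 23-covariate clinical table, and outcomes from
  P(mRS 3–6) = logistic(&beta;&#8320; + &beta;&#8346;z&#8346; +
  &beta;ᵥzᵥ + &beta;ₐzₐ + &beta;ₙzₙ) over standardised heterogeneity,
  lesion volume, age and 24-h NIHSS.

## Worked example

The `analysis/` scripts run the study as a four-stage workflow writing
everything under `results/` (the demo uses 40 patients so each stage takes
a minute or two; the full reference experiment is in
`scripts/acceptance.R`):

```sh
Rscript analysis/01_simulate_cohort.R 40 20260921
Rscript analysis/02_extract_features.R
Rscript analysis/03_evaluate_models.R
Rscript analysis/04_report.R
```

Stage 3/4 print, for this seed:

```
  feature_set          accuracy               auc
1         DWI 0.65 [0.52, 0.78] 0.71 [0.56, 0.86]
2       FLAIR 0.53 [0.46, 0.59] 0.62 [0.46, 0.79]
3     imaging 0.62 [0.52, 0.73] 0.69 [0.50, 0.88]
4    clinical 0.47 [0.24, 0.71] 0.51 [0.26, 0.77]
5 combination 0.68 [0.42, 0.93] 0.68 [0.39, 0.96]

== Top 10 predictors of the best model (mean |SHAP|) ==
                                      feature mean_abs_shap        kind
 DWI_gldm_LargeDependenceLowGrayLevelEmphasis         0.621     texture
                       DWI_firstorder_Maximum         0.347 first-order
                                DWI_glcm_Imc1         0.274     texture
                        DWI_glszm_ZoneEntropy         0.255     texture
 ...
```

Each row is one feature set's mean outer-fold metric with its 95%
t-interval; the SHAP ranking lists the predictors driving the best model
(texture features dominating indicates the lesion-heterogeneity signal was
recovered). At n = 40 the intervals are wide and the ordering noisy — at
the reference size n = 200 the combination set reliably outperforms the
single-source sets.

A minimal in-R session:

```r
library(strokeradiomics)
mask <- make_lesion_mask(grid_shape = c(40, 40, 22),
                         spacing = c(1.5, 1.5, 3),
                         radius_mm = 8, irregularity = 0.4, seed = 1)
vol <- make_texture_volume(mask, h = 0.6, seed = 2)
iso <- resample_isotropic(vol, mask, target_spacing = 1)
norm <- white_stripe_normalize(iso$volume)
feats <- extract_all(norm, iso$mask)
length(feats)                     # 107
feats["gldm_DependenceNonUniformityNormalized"]
```

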