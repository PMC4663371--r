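# morphodecode

Individual-level classification from whole-brain structural MRI. Given a
cohort of preprocessed (spatially normalized, smoothed) gray-matter
volumes with a binary diagnosis per subject — patients versus controls —
`morphodecode` asks: can the diagnosis be decoded from anatomy alone, and
*where* in the brain does the discriminating signal live?

The pipeline is the classic PCA + SVM multivoxel pattern analysis used in
clinical neuroimaging decoding studies:

1. **Preprocess** — Gaussian smoothing (FWHM → σ via
   `σ = FWHM / (2√(2 ln 2))`), masking, and flattening into a
   subjects × voxels matrix `X`.
2. **Feature extraction** — PCA of the centered matrix (at most `N − 1`
   components for `N` subjects); each subject becomes a short vector of
   PCA coefficients.
3. **Ranking** — coefficients ordered by Fisher Discriminant Ratio,
   `FDR = (μ₁ − μ₂)² / (σ₁² + σ₂²)`, a univariate class-separability
   score (not the false-discovery rate).
4. **Classification** — linear soft-margin SVM on the first `k` ranked
   coefficients, decision function `y(x) = Σₙ aₙ tₙ ⟨x, xₙ⟩ + b`.
5. **Evaluation** — stratified 20-fold / 10-fold cross-validation with
   per-fold feature fitting (no leakage) and pooled accuracy, specificity
   and sensitivity reported as functions of `k`.
6. **Maps** — the SVM weight vector back-projected to voxel space, plus
   the covariance-corrected activation pattern
   `a = cov(X) w / var(ŷ)` that makes decoder weights interpretable as
   sources; both normalizable to [0, 1] and thresholdable for display.

A synthetic cohort generator (shared smooth template + per-subject noise
+ a localized group effect with known ground-truth mask) makes the whole
pipeline testable end to end without any clinical data.

## Worked example

Simulate 17 patients and 17 controls on a 32³ grid (4 mm voxels) with a
weak planted effect (0.12 × noise SD in a 7-voxel-radius sphere), then
cross-validate and map:

```r
library(morphodecode)

cohort <- generate_cohort(cohort_config(effect_magnitude = 0.012, seed = 42))
#> <synthetic_cohort> 34 subjects (17 A / 17 B), grid 32x32x32, voxel 4x4x4 mm

fm  <- vectorize(smooth_cohort(cohort, fwhm_mm = 8))
#> <feature_matrix> 34 subjects x 32768 voxels (grid 32x32x32)

res <- run_cv(fm, n_folds = 20, seed = 7)
res
#> <cv_result> 20-fold CV over k = 1..31
#>   best: k = 27, accuracy 0.882, specificity 0.882, sensitivity 0.882

tidy(res)[c(1, 10, 27, 31), ]
#>       k     n n_correct accuracy specificity sensitivity convention
#>   1   1    34        18    0.529       0.529       0.529 standard
#>   2  10    34        27    0.794       0.765       0.824 standard
#>   3  27    34        30    0.882       0.882       0.882 standard
#>   4  31    34        29    0.853       0.882       0.824 standard
```

One FDR-ranked coefficient classifies at chance (0.53); accumulating
ranked coefficients raises the pooled accuracy to its best value 0.882
at `k = 27` of the 33 available — the typical rising-then-plateauing
metric curve (`autoplot(res)` draws all three metrics against `k`).
Sensitivity is the fraction of patients (group B, label +1) recovered,
specificity the fraction of controls (group A, label −1).

```r
maps <- fit_pattern_maps(fm, k = res$best$k)
top  <- top_fraction_mask(maps$activation, 0.05)
dice_overlap(top, cohort$effect_mask)
#> [1] 0.241
```

The top-5% voxels of the activation map overlap the planted ground-truth
sphere with Dice 0.24 at this weak effect; at the generator's default
effect (2 × noise SD) the same overlap is ≈ 0.93 and cross-validated
accuracy is 1.0. `threshold_map(normalize_map(maps$activation), 0.5)`
yields the display-ready 50%-thresholded map, and `write_map()` exports
any map as NIfTI with a JSON sidecar.

The whole chain — simulate → smooth → cross-validate (both schemes) →
maps → CSV/JSON/NIfTI export with a provenance manifest — runs from one
declarative config via `run_pipeline(pipeline_config(...))`, or from a
YAML file via `load_pipeline_config()`.

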