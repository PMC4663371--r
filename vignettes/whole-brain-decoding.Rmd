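---
title: "Whole-brain structural decoding: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain structural decoding: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodecode)
```

## The decoding model

`morphodecode` classifies individual subjects from preprocessed structural
brain volumes — spatially normalized, smoothed gray-matter maps of the kind
a standard VBM pipeline produces. The pipeline has four stages.

**Preprocessing.** Each subject volume is smoothed with a separable
Gaussian kernel; the per-axis standard deviation is
`fwhm / (voxel_size * 2 * sqrt(2 * log(2)))` voxels, and 8 mm isotropic
FWHM is the conventional default for gray-matter maps. Volumes are then
flattened into a subjects-by-voxels matrix, optionally restricted to a
mask (`"nonzero-any"` drops empty background; `"all"` keeps the literal
whole volume — both are supported because published pipelines are often
silent on this point).

**Feature extraction.** PCA on the mean-centered matrix yields at most
`N - 1` components with nonzero eigenvalue for `N` subjects; components
below a relative eigenvalue tolerance of `1e-10` of the largest are
treated as numerical noise and dropped. Because voxels vastly outnumber
subjects, the decomposition runs in sample space (eigendecomposition of
the n-by-n Gram matrix), which is algebraically identical to diagonalizing
the voxel covariance. Eigenvalues follow the sample-variance convention
(denominator `n - 1`), so training coefficient columns have variance
exactly equal to the eigenvalues — this makes the activation-map shortcut
below exact rather than approximate.

**Ranking and classification.** Each PCA coefficient is scored by its
Fisher Discriminant Ratio,
`FDR = (mu1 - mu2)^2 / (sigma1^2 + sigma2^2)`, a univariate class-
separability measure (distinct from the false-discovery rate), and
components are ordered by descending FDR with ties broken by ascending
component index for reproducibility. A linear soft-margin SVM is trained
on the first `k` ranked coefficients. The decision function is the dual
expansion `y(x) = sum_n a_n t_n <x, x_n> + b`; predictions are `sign(y)`
with the exact tie `y = 0` resolved to class `+1`. The soft-margin cost
`C` defaults to 1 (a conventional choice; on well-separated synthetic
cohorts the metric curves are insensitive to it), and only the linear
kernel is accepted — nonlinear kernels have no primal weight vector to
back-project into maps.

**Evaluation.** Stratified k-fold cross-validation (20-fold and 10-fold
are the typical schemes). Within each fold, PCA and the FDR ranking are
fitted on the training subjects only and test subjects are projected into
the training subspace — the only leakage-free reading of a per-fold
"separate feature extraction". Test predictions are pooled across folds
into a single confusion table per `k`, because the metrics count images
and pooling is the only reading consistent with a single total `N`;
accuracy, specificity and sensitivity are then reported as functions of
`k`, with the best operating point taken at the highest accuracy
(smallest `k` on ties).

Group-to-metric assignment: group A (label `-1`) plays the controls,
group B (label `+1`) the patients, so sensitivity refers to patients.
Besides the standard same-group rates, an `"as-printed"` convention with
cross-group denominators (`Specificity = A_CC / (A_CC + B_IC)`,
`Sensitivity = B_CC / (B_CC + A_IC)`) is available, because some published
formulations typeset the rates that way; the package defaults to
`"standard"` and never silently chooses for you when you ask otherwise.

## Discriminative maps

A linear decoder's weights live in coefficient space; two voxel-space maps
are derived from the final model (fitted on the full cohort, matching the
single summary map a study would publish — per-fold maps can be built by
calling `fit_pattern_maps()` on fold subsets).

The **weight map** multiplies each support sample's back-projected
(mean-free) brain by its SVM weight `a_n t_n` and sums voxelwise; this is
algebraically identical to back-projecting the primal weight
`w = sum a_n t_n x_n`, and the test suite asserts the identity at `1e-8`.
Back-projection for maps is mean-free by design: the training mean carries
average anatomy, not class information.

The **activation map** applies the forward-model correction for backward
models: `a = cov(X) w / var(y_hat)`. Decoder weights alone are not
interpretable as sources — a voxel can receive weight purely to cancel
noise. Since training PCA coefficients are uncorrelated with variances
equal to the eigenvalues, the pattern reduces to
`a_j = lambda_j w_j / var(y_hat)` in coefficient space before
back-projection; `var(y_hat)` uses denominator `n - 1`, matching the
eigenvalue convention, so the shortcut equals the dense-covariance
definition exactly (asserted against a brute-force oracle in the tests).

For display, maps are normalized to `[0, 1]` — by default on magnitudes
(`"abs-minmax"`, matching a single-color-scale display; a signed affine
mode is available) — and thresholded (e.g. at 50%) to keep only the most
discriminative voxels.

## The synthetic cohort generator

The generator emulates exactly the statistical structure the analysis
assumes: a shared smooth template (an ellipsoid softened by an 8 mm
Gaussian, standing in for a smoothed gray-matter probability map), i.i.d.
per-voxel Gaussian noise per subject, and a smooth, localized additive
effect applied to group B, whose unsmoothed support is returned as a
ground-truth mask. Noise is added after template construction; per-subject
smoothing belongs to the preprocessing stage, keeping generator and
preprocessing responsibilities separate.

Defaults were fixed once, up front: 17 + 17 subjects on a 32-cubed grid at
4 mm voxels (a head-sized 128 mm field of view at desk scale; the full
121 x 145 x 121 grid is available by config), noise SD 0.1 intensity
units, effect magnitude `2 * noise_sd` in a single sphere of radius 7
voxels (about 4% of the grid, so a top-5% map-overlap score is
geometrically attainable), construction-time FWHM 8 mm. The intensity
distribution of real nonmodulated VBM output is not publicly
characterized; the ellipsoid template is a stand-in, not a claim about
real data.

What passing tests on this generator do show: the pipeline recovers known,
localized, smooth group differences, stays at chance when there is none,
and its maps point at the planted region. What they cannot show: behavior
under realistic anatomy, inter-subject registration error, bias fields,
or correlated noise — none of which are simulated.

## Numerical choices

- **Convolution boundary**: whole-sample symmetric reflection (edge voxel
  repeated), which conserves total intensity for the unit-mass kernel and
  avoids energy loss at brain edges on small grids; kernels are truncated
  at 4 sigma and renormalized.
- **Eigenvalue cutoff**: `lambda / lambda_max > 1e-10`, the floating-point
  numerical-rank criterion.
- **FDR degeneracies**: zero pooled variance with distinct means scores
  `+Inf` (ranked first); with equal means, 0.
- **SVM solver**: libsvm with feature scaling disabled and termination
  tolerance `1e-8`, tight enough that the dual solution matches an
  independent interior-point QP solve to `1e-6`. libsvm's decision-value
  sign follows the class of the first training sample; the wrapper
  canonicalizes so positive always means `+1`.
- **Folds**: within each class, subjects are shuffled (seeded) and dealt
  round-robin, the second class continuing where the first stopped — so no
  fold is empty even when folds outnumber a class (34 subjects in 20
  folds), and per-class fold sizes differ by at most 1. When a fold's
  training set supports fewer than the requested `k` components, the fold
  uses all it has and the substitution is logged, so curves can extend to
  `k` values that small folds cannot supply.
- **Null calibration** is evaluated at a single pre-specified `k` (the
  largest usable), not at the best over the curve: maximizing over ~30
  correlated accuracies biases a null check upward, and the terminal point
  is the pipeline's natural fixed operating point.
- **Zero metric denominators** yield `NA`, never a silent 0.
- **Determinism**: every stochastic stage takes an explicit seed, RNG state
  is restored after use, and NIfTI outputs are written uncompressed so
  identical configs reproduce outputs byte for byte.

## Problem sizes

The package's own test and demonstration cohorts run at 17 + 17 subjects
on 32-cubed grids (single-fold fits in well under a second; a full
20-fold, all-`k` cross-validation in a few seconds), with smaller
16-cubed cohorts for property tests across many seeds. These sizes give
the same component-count laws and recovery behavior as the full-resolution
grid, which remains available through `cohort_config(grid_shape =
c(121, 145, 121), voxel_size_mm = c(1.5, 1.5, 1.5))`.

## Known limitations

- The generator's groups differ by a single additive smooth effect;
  multi-focal, interacting or variance-changing effects are configurable
  only as unions of spheres.
- No nested cross-validation: `C` and `k` are not tuned inside folds, so
  the best-`k` triple is an optimistic operating point, as it is in the
  analyses this pipeline mirrors.
- No statistical inference on map values (no permutation p-values); maps
  are descriptive.
- Real-data preprocessing upstream of smoothing (segmentation, nonlinear
  normalization, skull-stripping) is out of scope; the pipeline consumes
  already-normalized volumes.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  cohort = cohort_config(seed = 42),
  cv_schemes = c(20, 10),
  output_dir = tempfile("decode_run_")
)
report <- run_pipeline(cfg)
glance(report$cv$`20fold`)
autoplot(report$cv$`20fold`)
```
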