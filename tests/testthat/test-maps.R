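fit_small <- function(seed = 50, k = 6, n_a = 10, n_b = 10, ...) {
  cohort <- tiny_cohort(n_a = n_a, n_b = n_b, seed = seed, ...)
  fm <- tiny_fm(cohort)
  c(fit_pattern_maps(fm, k = k), list(fm = fm, cohort = cohort))
}

test_that("sample-summation weight map equals primal-weight back-projection", {
  f <- fit_small(seed = 51)
  # independent route: back-project w = sum a_n t_n x_n directly
  primal <- drop(back_project(f$pca, f$svm$weights, f$components))
  primal_map <- unflatten(primal, f$fm)
  scale <- max(abs(primal_map))
  expect_lt(max(abs(f$weight$data - primal_map)) / scale, 1e-8)
})

test_that("a model with all-zero dual weights yields the zero map", {
  f <- fit_small(seed = 52)
  m <- f$svm
  m$dual_weights <- rep(0, length(m$dual_weights))
  wm <- weight_map(m, f$pca, f$fm, f$components)
  expect_true(all(wm$data == 0))
})

test_that("whitened coefficients make activation and weight maps collinear", {
  f <- fit_small(seed = 53)
  pca <- f$pca
  pca$eigenvalues[f$components] <- 1  # identity coefficient covariance
  co <- project(pca, f$fm)[, f$components, drop = FALSE]
  am <- haufe_activation_map(f$svm, pca, f$fm, co, f$components)
  wm <- weight_map(f$svm, pca, f$fm, f$components)
  cosine <- sum(am$data * wm$data) /
    sqrt(sum(am$data^2) * sum(wm$data^2))
  expect_equal(cosine, 1, tolerance = 1e-8)
})

test_that("coefficient-space shortcut equals the brute-force covariance pattern", {
  # small instance: n = 10, 3 components, dense covariance oracle
  cohort <- tiny_cohort(n_a = 5, n_b = 5, grid = 8, radius = 2,
                        center = c(5, 5, 5), seed = 54)
  fm <- tiny_fm(cohort)
  pca <- fit_pca(fm)
  co <- project(pca, fm)
  sel <- 1:3
  m <- svm_train(co[, sel], fm$labels, cost = 1)
  yhat <- decision_value(m, co[, sel])
  a_oracle <- drop(cov(co[, sel]) %*% m$weights) / var(yhat)
  a_short <- pca$eigenvalues[sel] * m$weights / var(yhat)
  expect_lt(max(abs(a_short - a_oracle)), 1e-6)
  # and the voxel-space map built from the shortcut matches the oracle's
  am <- haufe_activation_map(m, pca, fm, co[, sel], sel)
  oracle_map <- unflatten(drop(back_project(pca, a_oracle, sel)), fm)
  expect_lt(max(abs(am$data - oracle_map)), 1e-6 * max(abs(oracle_map)))
})

test_that("flipping all training labels negates both maps voxelwise", {
  cohort <- tiny_cohort(seed = 55)
  fm <- tiny_fm(cohort)
  fm2 <- fm
  fm2$labels <- -fm$labels
  f1 <- fit_pattern_maps(fm, k = 5)
  f2 <- fit_pattern_maps(fm2, k = 5)
  expect_equal(f2$weight$data, -f1$weight$data, tolerance = 1e-8)
  expect_equal(f2$activation$data, -f1$activation$data, tolerance = 1e-8)
})

test_that("strong planted effects localize: top-5% activation overlaps the mask", {
  f <- fit_small(seed = 56, n_a = 17, n_b = 17)
  top <- top_fraction_mask(f$activation, 0.05)
  expect_gte(dice_overlap(top, f$cohort$effect_mask), 0.3)
})

test_that("activation peak falls inside the effect mask across seeds", {
  hits <- sapply(1:10, function(s) {
    f <- fit_small(seed = 500 + s)
    peak <- which.max(abs(f$activation$data))
    f$cohort$effect_mask[peak] > 0
  })
  expect_gte(sum(hits), 8)
})

test_that("normalization maps magnitudes onto [0, 1] as defined", {
  mk <- function(v) morphodecode:::new_voxel_map(array(v, c(1, 1, length(v))),
                                                 "weight")
  nm <- normalize_map(mk(c(-4, 0, 2)), "abs-minmax")
  expect_equal(as.vector(nm$data), c(1, 0, 0.5))
  set.seed(57)
  nm2 <- normalize_map(mk(rnorm(50)))
  expect_equal(range(nm2$data), c(0, 1))
  # signed mode is idempotent on a map already spanning [0, 1]
  already <- mk(c(0, 0.3, 1))
  expect_equal(normalize_map(already, "signed-minmax")$data, already$data)
  expect_error(normalize_map(mk(rep(2, 5))), "constant")
})

test_that("thresholding keeps exactly the voxels at or above the cut", {
  mk <- function(v) morphodecode:::new_voxel_map(array(v, c(1, 1, length(v))),
                                                 "normalized")
  tm <- threshold_map(mk(c(0, 0.25, 0.5, 0.75, 1)), 0.5)
  expect_equal(tm$info$n_surviving, 3)
  expect_equal(as.vector(tm$data), c(0, 0, 0.5, 0.75, 1))
  # threshold 0: everything survives unchanged
  t0 <- threshold_map(mk(c(0, 0.2, 1)), 0)
  expect_equal(as.vector(t0$data), c(0, 0.2, 1))
  # threshold 1: only the maximum survives
  t1 <- threshold_map(mk(c(0, 0.2, 1)), 1)
  expect_equal(t1$info$n_surviving, 1)
  raw <- morphodecode:::new_voxel_map(array(1:4, c(1, 1, 4)), "weight")
  expect_error(threshold_map(raw, 0.5), "normalized")
})

test_that("maps round-trip through NIfTI with their sidecar", {
  f <- fit_small(seed = 58)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "w.nii")
  write_map(f$weight, p, f$fm$voxel_size_mm)
  img <- RNifti::readNifti(p)
  expect_equal(array(as.numeric(img), dim = dim(img)), f$weight$data,
               tolerance = 1e-6)
  sidecar <- jsonlite::read_json(file.path(dir, "w.json"))
  expect_equal(sidecar$kind, "weight")
})
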