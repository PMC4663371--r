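new_voxel_map <- function(data, kind, info = list()) {
  structure(list(data = data, kind = kind, info = info), class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  cat(sprintf("<voxel_map:%s> grid %s, range [%.4g, %.4g]\n",
              x$kind, paste(dim(x$data), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' SVM weight map in voxel space
#'
#' Builds the discriminative weight map by multiplying each support
#' sample's back-projected (mean-free) brain with its SVM weight
#' `a_n t_n` and summing voxelwise:
#' `map = sum_n (a_n t_n) * back_project(coefficients_n)`. Algebraically
#' this equals the back-projection of the primal weight vector
#' `w = sum_n a_n t_n x_n`, a property the test suite asserts.
#'
#' @param model A `linear_svm` trained on coefficients over
#'   `component_subset` of `pca`.
#' @param pca The `pca_fit` the coefficients came from.
#' @param fm The `feature_matrix` defining the voxel grid.
#' @param component_subset Components (in `pca`) the SVM features refer
#'   to, in SVM feature order.
#' @return A `voxel_map` of kind `"weight"`.
#' @export
weight_map <- function(model, pca, fm,
                       component_subset = seq_along(pca$eigenvalues)) {
  if (model$n_features != length(component_subset))
    stopf("model has %d features but component_subset has %d",
          model$n_features, length(component_subset))
  at <- model$dual_weights * model$support_labels
  # sample-summation route: weighted sum of back-projected support brains
  acc <- numeric(length(pca$mean_vector))
  for (i in seq_along(at)) {
    acc <- acc + at[i] * drop(back_project(pca, model$support_samples[i, ],
                                           component_subset))
  }
  new_voxel_map(unflatten(acc, fm), "weight",
                list(cost = model$cost, components = component_subset))
}

#' Covariance-corrected activation pattern map
#'
#' Decoder weights of a backward model are not directly interpretable as
#' sources; the corresponding forward-model activation pattern is
#' `a = cov(X) w / var(y_hat)`. Because training PCA coefficients are
#' uncorrelated with variances equal to the eigenvalues, the pattern in
#' coefficient space reduces to `a_j = lambda_j w_j / var(y_hat)`, which
#' is then back-projected (mean-free) to voxel space. `var(y_hat)` is the
#' sample variance (denominator n-1, matching the eigenvalue convention)
#' of the decision values over the training set.
#'
#' @inheritParams weight_map
#' @param training_coefficients The training coefficient matrix the SVM
#'   was fitted on (columns = `component_subset`), used to compute
#'   `var(y_hat)`.
#' @return A `voxel_map` of kind `"activation"`.
#' @export
haufe_activation_map <- function(model, pca, fm, training_coefficients,
                                 component_subset = seq_along(pca$eigenvalues)) {
  w <- model$weights
  yhat <- decision_value(model, training_coefficients)
  v <- stats::var(yhat)
  if (v <= 0) stopf("degenerate classifier: training decision values are constant")
  a_coef <- pca$eigenvalues[component_subset] * w / v
  new_voxel_map(
    unflatten(drop(back_project(pca, a_coef, component_subset)), fm),
    "activation",
    list(var_yhat = v, components = component_subset)
  )
}

#' Normalize a voxel map to the unit interval
#'
#' @param map A `voxel_map`.
#' @param mode `"abs-minmax"` (default) rescales the magnitudes:
#'   `v <- (|v| - min|v|) / (max|v| - min|v|)`, matching a single-color-
#'   scale magnitude display; `"signed-minmax"` maps the raw values
#'   affinely onto `[0, 1]`.
#' @return A `voxel_map` of kind `"normalized"` with min exactly 0 and
#'   max exactly 1.
#' @export
normalize_map <- function(map, mode = c("abs-minmax", "signed-minmax")) {
  mode <- match.arg(mode)
  v <- map$data
  if (mode == "abs-minmax") v <- abs(v)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stopf("cannot normalize a constant map")
  new_voxel_map((v - lo) / (hi - lo), "normalized",
                c(map$info, list(mode = mode)))
}

#' Threshold a normalized voxel map
#'
#' Retains voxels whose normalized value is at least `threshold`, zeroing
#' the rest, for display of the most discriminative anatomy (e.g. a 50%
#' threshold).
#'
#' @param map A `voxel_map` of kind `"normalized"`.
#' @param threshold Fraction in `[0, 1]`.
#' @return A `voxel_map` of kind `"thresholded"`; the number of surviving
#'   voxels is in `info$n_surviving`.
#' @export
threshold_map <- function(map, threshold = 0.5) {
  if (!inherits(map, "voxel_map") || map$kind != "normalized")
    stopf("threshold_map requires a normalized voxel_map")
  if (threshold < 0 || threshold > 1) stopf("threshold must be in [0, 1]")
  out <- map$data
  out[out < threshold] <- 0
  new_voxel_map(out, "thresholded",
                c(map$info, list(threshold = threshold,
                                 n_surviving = sum(out > 0))))
}

#' Mask of the top fraction of map magnitudes
#'
#' Convenience for localization scoring: marks the `fraction` of voxels
#' with the largest absolute map values.
#'
#' @param map A `voxel_map` or 3D array.
#' @param fraction Fraction of voxels to keep (e.g. 0.05).
#' @return A binary array of the map's shape.
#' @export
top_fraction_mask <- function(map, fraction = 0.05) {
  v <- if (inherits(map, "voxel_map")) map$data else map
  a <- abs(as.vector(v))
  n_keep <- max(1L, floor(length(a) * fraction))
  cut <- sort(a, decreasing = TRUE)[n_keep]
  array(as.numeric(abs(v) >= cut), dim = dim(v))
}

#' Write a voxel map as NIfTI with a JSON sidecar
#'
#' @param map A `voxel_map`.
#' @param path Output path ending in `.nii`.
#' @param voxel_size_mm Voxel size for the affine.
#' @return Invisibly, the NIfTI path.
#' @export
write_map <- function(map, path, voxel_size_mm) {
  write_volume(map$data, voxel_size_mm, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(c(list(kind = map$kind), map$info), sidecar,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Train the final model and derive both discriminative maps
#'
#' Fits PCA, the Fisher-ratio ranking and the SVM on the full cohort
#' (matching the single published-style map, rather than per-fold maps),
#' using the first `k` ranked coefficients, and returns the raw weight
#' map and the covariance-corrected activation map.
#'
#' @param fm A `feature_matrix` (with labels).
#' @param k Number of FDR-ranked coefficients for the final model
#'   (default: all available).
#' @param cost SVM cost.
#' @return List with `weight` and `activation` (`voxel_map`s), plus the
#'   fitted `pca`, `ranking`, `svm` and the component subset used.
#' @export
fit_pattern_maps <- function(fm, k = NULL, cost = 1) {
  pca <- fit_pca(fm)
  co <- project(pca, fm)
  ranking <- fdr_rank(co, fm$labels)
  k <- min(k %||% ncol(co), ncol(co))
  sel <- ranking$order[seq_len(k)]
  co_sel <- co[, sel, drop = FALSE]
  m <- svm_train(co_sel, fm$labels, cost = cost)
  list(
    weight = weight_map(m, pca, fm, sel),
    activation = haufe_activation_map(m, pca, fm, co_sel, sel),
    pca = pca, ranking = ranking, svm = m, components = sel
  )
}
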