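#' Fit a principal component subspace to a feature matrix
#'
#' Learns the PCA model of the mean-centered subjects-by-voxels matrix.
#' Because the voxel count vastly exceeds the subject count, the
#' decomposition is done in sample space: the n x n Gram matrix of the
#' centered data is eigendecomposed and voxel-space components are
#' recovered from its eigenvectors — mathematically identical to the
#' eigendecomposition of the voxel covariance, at a fraction of the cost.
#'
#' At most `n - 1` components can carry nonzero variance (centering removes
#' one degree of freedom); components whose eigenvalue falls below
#' `tol` times the largest are treated as numerically null and dropped.
#' Eigenvalues are reported as sample variances (denominator `n - 1`) of
#' the training coefficients, so `project()`ed training columns have
#' variance exactly equal to the eigenvalues.
#'
#' @param x A `feature_matrix` from [vectorize()], or a bare numeric matrix
#'   (subjects in rows).
#' @param tol Relative eigenvalue cutoff for numerical rank
#'   (default `1e-10`).
#' @return An object of class `pca_fit`: list with `mean_vector`,
#'   `components` (n_components x n_features, orthonormal rows, ordered by
#'   nonincreasing eigenvalue), `eigenvalues`, `n_training_samples`.
#' @export
fit_pca <- function(x, tol = 1e-10) {
  X <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  n <- nrow(X)
  if (n < 2L) stopf("PCA requires at least 2 samples, got %d", n)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  G <- tcrossprod(Xc)                     # n x n Gram matrix
  eg <- eigen(G, symmetric = TRUE)
  d2 <- pmax(eg$values, 0)
  keep <- which(d2 > tol * max(d2) & d2 > 0)
  keep <- keep[seq_len(min(length(keep), n - 1L))]
  d <- sqrt(d2[keep])
  # voxel-space loadings: v_j = Xc' u_j / ||Xc' u_j||
  comps <- crossprod(Xc, eg$vectors[, keep, drop = FALSE])
  comps <- sweep(comps, 2L, d, `/`)
  structure(
    list(
      mean_vector = mu,
      components = t(comps),
      eigenvalues = d2[keep] / (n - 1L),
      n_training_samples = n
    ),
    class = "pca_fit"
  )
}

#' Project samples into a fitted PCA subspace
#'
#' Computes the PCA coefficients `(X - mean) %*% t(components)`. Applies
#' equally to the training set and to held-out samples, which is how test
#' folds are embedded into the training subspace without refitting.
#'
#' @param model A `pca_fit`.
#' @param x A `feature_matrix` or numeric matrix with the same feature
#'   count the model was fitted on.
#' @return An n_samples x n_components coefficient matrix.
#' @export
project <- function(model, x) {
  X <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  if (ncol(X) != length(model$mean_vector))
    stopf("feature count mismatch: model has %d, data has %d",
          length(model$mean_vector), ncol(X))
  sweep(X, 2L, model$mean_vector) %*% t(model$components)
}

#' Back-project PCA coefficients to voxel space
#'
#' Reconstructs voxel-space rows from coefficients over a subset of
#' components: `sum_j coeff_j * component_j`, plus the training mean when
#' `include_mean = TRUE`. The mean-free form (default) is what
#' discriminative maps use — the training mean carries average anatomy,
#' not class information.
#'
#' @param model A `pca_fit`.
#' @param coefficients Matrix (or vector) of coefficients, one column per
#'   element of `component_subset`.
#' @param component_subset Integer indices of the components the
#'   coefficient columns refer to (default: all).
#' @param include_mean Add the training mean vector to each reconstruction?
#' @return An n_samples x n_features matrix of voxel-space rows.
#' @export
back_project <- function(model, coefficients,
                         component_subset = seq_along(model$eigenvalues),
                         include_mean = FALSE) {
  if (any(component_subset < 1L) || any(component_subset > nrow(model$components)))
    stopf("component_subset contains indices outside 1..%d", nrow(model$components))
  co <- if (is.null(dim(coefficients))) matrix(coefficients, nrow = 1L)
        else as.matrix(coefficients)
  if (ncol(co) != length(component_subset))
    stopf("coefficients have %d columns but component_subset has %d entries",
          ncol(co), length(component_subset))
  rec <- co %*% model$components[component_subset, , drop = FALSE]
  if (include_mean) rec <- sweep(rec, 2L, model$mean_vector, `+`)
  rec
}

#' @export
print.pca_fit <- function(x, ...) {
  cat(sprintf("<pca_fit> %d components from %d samples x %d features\n",
              length(x$eigenvalues), x$n_training_samples,
              length(x$mean_vector)))
  invisible(x)
}

#' Tidy a fitted PCA model
#'
#' @param x A `pca_fit`.
#' @param ... Unused.
#' @return A tibble with one row per component: `component`, `eigenvalue`,
#'   `variance_pct` and `cumulative_variance_pct` (percent of total
#'   retained variance).
#' @export
tidy.pca_fit <- function(x, ...) {
  pct <- 100 * x$eigenvalues / sum(x$eigenvalues)
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_pct = pct,
    cumulative_variance_pct = cumsum(pct)
  )
}

#' @export
glance.pca_fit <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$eigenvalues),
    n_training_samples = x$n_training_samples,
    n_features = length(x$mean_vector),
    first_component_variance_pct = 100 * x$eigenvalues[1] / sum(x$eigenvalues)
  )
}
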