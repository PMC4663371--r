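# Discrete Gaussian kernel normalized to unit mass. Truncated at 4 sigma,
# matching common neuroimaging practice; sum preservation is exact because
# the kernel is renormalized after truncation.
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Map an arbitrary integer index onto 1..n by whole-sample symmetric
# reflection (edge voxel repeated), folding as often as needed.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n
  j <- (i - 1L) %% p
  ifelse(j < n, j + 1L, p - j)
}

convolve_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  dp <- dim(a)
  n <- dp[1]
  a <- matrix(a, nrow = n)
  r <- (length(kernel) - 1L) %/% 2L
  padded <- a[reflect_index(seq.int(1L - r, n + r), n), , drop = FALSE]
  out <- matrix(0, n, ncol(a))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * padded[j:(j + n - 1L), , drop = FALSE]
  }
  aperm(array(out, dp), order(perm))
}

# Core separable convolution on a bare 3D array; fwhm may be scalar or
# per-axis, in mm.
gaussian_smooth_array <- function(arr, fwhm_mm, voxel_size_mm) {
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3L)
  if (any(fwhm_mm < 0)) stopf("fwhm_mm must be nonnegative")
  if (any(!is.finite(fwhm_mm))) stopf("fwhm_mm must be finite")
  sigma_vox <- fwhm_mm / (as.numeric(voxel_size_mm) * 2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    arr <- convolve_axis(arr, gaussian_kernel_1d(sigma_vox[axis]), axis)
  }
  arr
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian convolution with per-axis standard deviation
#' `sigma = fwhm / (voxel_size * 2 * sqrt(2 * log(2)))` voxels, the usual
#' FWHM-to-sigma conversion for structural image smoothing. The boundary is
#' handled by symmetric reflection, which preserves total intensity for the
#' unit-mass kernel.
#'
#' @param volume A 3D numeric array.
#' @param fwhm_mm Full width at half maximum in mm; scalar or one value per
#'   axis. Zero means no smoothing on that axis.
#' @param voxel_size_mm Voxel edge lengths in mm (3 positive reals).
#' @return A smoothed 3D array of the same dimensions.
#' @export
#' @examples
#' v <- array(0, c(16, 16, 16)); v[8, 8, 8] <- 1
#' s <- gaussian_smooth(v, fwhm_mm = 8, voxel_size_mm = c(2, 2, 2))
#' abs(sum(s) - 1) < 1e-6
gaussian_smooth <- function(volume, fwhm_mm, voxel_size_mm) {
  if (any(voxel_size_mm <= 0)) stopf("voxel_size_mm must be positive")
  gaussian_smooth_array(volume, fwhm_mm, voxel_size_mm)
}

#' Smooth every volume of a cohort
#'
#' Applies [gaussian_smooth()] to each subject volume. Smoothing is a
#' per-subject, label-free operation, so doing it once before any
#' cross-validation split cannot leak test information into training.
#'
#' @param cohort A cohort list as returned by [generate_cohort()] or
#'   [read_cohort()].
#' @param fwhm_mm FWHM in mm (scalar or per-axis); the reference protocol
#'   value for whole-brain gray-matter maps is 8 mm isotropic.
#' @return The cohort with smoothed volumes.
#' @export
smooth_cohort <- function(cohort, fwhm_mm = 8) {
  cohort$volumes <- lapply(cohort$volumes, gaussian_smooth,
                           fwhm_mm = fwhm_mm,
                           voxel_size_mm = cohort$voxel_size_mm)
  cohort
}

#' Build a voxel inclusion mask for a cohort
#'
#' @param cohort A cohort list (nonempty `volumes`).
#' @param strategy `"nonzero-any"` (default) keeps voxels nonzero in at
#'   least one subject, excluding empty background; `"all"` keeps every
#'   voxel, i.e. the literal whole-volume feature set.
#' @return A binary 3D array.
#' @export
build_mask <- function(cohort, strategy = c("nonzero-any", "all")) {
  strategy <- match.arg(strategy)
  if (length(cohort$volumes) == 0L) stopf("cohort has no volumes")
  d <- dim(cohort$volumes[[1]])
  if (strategy == "all") return(array(1, dim = d))
  any_nz <- array(FALSE, dim = d)
  for (v in cohort$volumes) any_nz <- any_nz | (v != 0)
  array(as.numeric(any_nz), dim = d)
}

#' Flatten cohort volumes into a subjects-by-voxels feature matrix
#'
#' Rows follow the input subject order; columns follow R's column-major
#' raster order of the masked voxel coordinates (x fastest). The mapping is
#' a bijection onto masked voxels, inverted exactly by [unflatten()].
#'
#' @param cohort A cohort list.
#' @param mask Binary 3D array (default: [build_mask()] with its default
#'   strategy). Must match the volume grid.
#' @return An object of class `feature_matrix`: a list with `values`
#'   (n_subjects x n_features matrix, rows named by subject), `mask`,
#'   `feature_index` (linear voxel index of each column), `subject_ids`,
#'   `labels` and `voxel_size_mm`.
#' @export
vectorize <- function(cohort, mask = build_mask(cohort)) {
  idx <- which(mask != 0)
  vals <- matrix(0, nrow = length(cohort$volumes), ncol = length(idx),
                 dimnames = list(names(cohort$volumes), NULL))
  for (i in seq_along(cohort$volumes)) {
    v <- cohort$volumes[[i]]
    if (!identical(dim(v), dim(mask)))
      stopf("subject '%s' has shape [%s], mask is [%s]",
            names(cohort$volumes)[i],
            paste(dim(v), collapse = "x"), paste(dim(mask), collapse = "x"))
    vals[i, ] <- v[idx]
  }
  structure(
    list(
      values = vals,
      mask = mask,
      feature_index = idx,
      subject_ids = names(cohort$volumes),
      labels = cohort$labels$label,
      voxel_size_mm = cohort$voxel_size_mm
    ),
    class = "feature_matrix"
  )
}

#' Restore a feature vector to a 3D volume
#'
#' Inverse of the flattening performed by [vectorize()]: masked voxels get
#' the vector's values, all other voxels are zero.
#'
#' @param values Numeric vector of length `n_features`.
#' @param fm A `feature_matrix` (provides mask and column-to-voxel map).
#' @return A 3D array on the cohort grid.
#' @export
unflatten <- function(values, fm) {
  if (length(values) != length(fm$feature_index))
    stopf("expected %d values, got %d", length(fm$feature_index), length(values))
  out <- array(0, dim = dim(fm$mask))
  out[fm$feature_index] <- values
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects x %d voxels (grid %s)\n",
              nrow(x$values), ncol(x$values),
              paste(dim(x$mask), collapse = "x")))
  invisible(x)
}
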