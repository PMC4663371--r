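#' Configuration for a synthetic structural-volume cohort
#'
#' Describes a two-group cohort of 3D gray-matter-like volumes: a shared
#' smooth template, i.i.d. Gaussian voxel noise per subject, and a smooth,
#' spatially localized additive effect applied to group B only. The effect
#' support (before smoothing) is returned as a ground-truth mask so that
#' discriminative maps can be scored against it.
#'
#' Group labels follow a fixed convention: group A is labelled `-1`
#' (playing the role of healthy controls), group B `+1` (patients).
#'
#' @param n_group_a,n_group_b Number of subjects per group (each >= 1).
#' @param grid_shape Integer vector of 3 positive voxel counts.
#'   Default `c(32, 32, 32)`, a desk-scale stand-in for the full
#'   121 x 145 x 121 grid of spatially normalized brain volumes.
#' @param voxel_size_mm Numeric vector of 3 positive voxel edge lengths in
#'   mm. Default 4 mm isotropic so the default grid spans a
#'   head-sized 128 mm field of view.
#' @param noise_sd Standard deviation of the per-voxel Gaussian noise, in
#'   intensity units.
#' @param effect_magnitude Intensity added to group B inside the effect
#'   regions (before smoothing of the effect field). Zero means both groups
#'   are drawn from the identical distribution.
#' @param effect_regions List of spherical regions, each
#'   `list(center = c(x, y, z), radius = r)` in voxel units. Every region
#'   must lie fully inside the grid.
#' @param template_kind `"ellipsoid"` (smooth brain-like blob, default) or
#'   `"flat"` (constant 1 everywhere, for analytic tests).
#' @param smoothing_fwhm_mm Full width at half maximum, in mm, of the
#'   Gaussian applied to the template and the effect field at construction
#'   time (keeps the planted effect smooth, like real morphometric
#'   differences). This is distinct from the per-subject smoothing done by
#'   [gaussian_smooth()] during preprocessing.
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [write_cohort()]
#' @export
cohort_config <- function(n_group_a = 17,
                          n_group_b = 17,
                          grid_shape = c(32L, 32L, 32L),
                          voxel_size_mm = c(4, 4, 4),
                          noise_sd = 0.1,
                          effect_magnitude = 0.2,
                          effect_regions = list(list(center = c(20, 19, 16), radius = 7)),
                          template_kind = c("ellipsoid", "flat"),
                          smoothing_fwhm_mm = 8,
                          seed = 1L) {
  template_kind <- match.arg(template_kind)
  cfg <- structure(
    list(
      n_group_a = as.integer(n_group_a),
      n_group_b = as.integer(n_group_b),
      grid_shape = as.integer(grid_shape),
      voxel_size_mm = as.numeric(voxel_size_mm),
      noise_sd = as.numeric(noise_sd),
      effect_magnitude = as.numeric(effect_magnitude),
      effect_regions = effect_regions,
      template_kind = template_kind,
      smoothing_fwhm_mm = as.numeric(smoothing_fwhm_mm),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_group_a < 1L) stopf("n_group_a must be >= 1, got %d", cfg$n_group_a)
  if (cfg$n_group_b < 1L) stopf("n_group_b must be >= 1, got %d", cfg$n_group_b)
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 1L))
    stopf("grid_shape must be 3 positive integers")
  if (length(cfg$voxel_size_mm) != 3L || any(cfg$voxel_size_mm <= 0))
    stopf("voxel_size_mm must be 3 positive reals")
  if (cfg$noise_sd < 0) stopf("noise_sd must be nonnegative, got %g", cfg$noise_sd)
  if (cfg$smoothing_fwhm_mm < 0) stopf("smoothing_fwhm_mm must be nonnegative")
  for (i in seq_along(cfg$effect_regions)) {
    reg <- cfg$effect_regions[[i]]
    if (is.null(reg$center) || is.null(reg$radius) || length(reg$center) != 3L)
      stopf("effect_regions[[%d]] must have a 3-vector center and a radius", i)
    lo <- reg$center - reg$radius
    hi <- reg$center + reg$radius
    if (any(lo < 1) || any(hi > cfg$grid_shape))
      stopf("effect_regions[[%d]] extends outside grid_shape [%s]",
            i, paste(cfg$grid_shape, collapse = " x "))
  }
  invisible(cfg)
}

# Smooth ellipsoid of intensity 1 inside, 0 outside, softened by a Gaussian:
# mimics a smoothed whole-brain gray-matter probability map.
make_template <- function(cfg) {
  d <- cfg$grid_shape
  if (cfg$template_kind == "flat") return(array(1, dim = d))
  ctr <- (d + 1) / 2
  semi <- d * 0.38
  ax <- outer(
    outer(((seq_len(d[1]) - ctr[1]) / semi[1])^2,
          ((seq_len(d[2]) - ctr[2]) / semi[2])^2, `+`),
    ((seq_len(d[3]) - ctr[3]) / semi[3])^2, `+`
  )
  tpl <- array(as.numeric(ax <= 1), dim = d)
  gaussian_smooth_array(tpl, cfg$smoothing_fwhm_mm, cfg$voxel_size_mm)
}

# Union of spherical indicators: the ground-truth support of the effect.
make_effect_mask <- function(cfg) {
  d <- cfg$grid_shape
  mask <- array(0, dim = d)
  for (reg in cfg$effect_regions) {
    dist2 <- outer(
      outer((seq_len(d[1]) - reg$center[1])^2,
            (seq_len(d[2]) - reg$center[2])^2, `+`),
      (seq_len(d[3]) - reg$center[3])^2, `+`
    )
    mask[dist2 <= reg$radius^2] <- 1
  }
  mask
}

#' Generate a synthetic two-group cohort of brain-like volumes
#'
#' Draws `n_group_a + n_group_b` volumes as
#' `template + effect_field + noise` (group B) or `template + noise`
#' (group A), where the effect field is the configured spherical support
#' convolved with a Gaussian of the configured FWHM and scaled to
#' `effect_magnitude`. The unsmoothed binary support is returned as the
#' ground-truth `effect_mask`.
#'
#' The generator is deterministic: the same config (including seed) always
#' produces bit-identical volumes, and it leaves the caller's RNG state
#' untouched.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: a list with
#'   \describe{
#'     \item{volumes}{named list of 3D arrays, one per subject.}
#'     \item{labels}{a tibble with `subject_id`, `group` and `label`
#'       (`-1` for group A, `+1` for group B).}
#'     \item{effect_mask}{binary 3D array marking the planted effect
#'       support.}
#'     \item{voxel_size_mm, config}{geometry and provenance.}
#'   }
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_group_a = 4, n_group_b = 4,
#'                                         grid_shape = c(12, 12, 12),
#'                                         effect_regions = list(
#'                                           list(center = c(6, 6, 6), radius = 3))))
#' length(cohort$volumes)
#' table(cohort$labels$label)
generate_cohort <- function(config) {
  validate_cohort_config(config)
  template <- make_template(config)
  mask <- make_effect_mask(config)
  effect <- gaussian_smooth_array(mask, config$smoothing_fwhm_mm,
                                  config$voxel_size_mm)
  if (max(effect) > 0) effect <- effect / max(effect) * config$effect_magnitude

  n <- config$n_group_a + config$n_group_b
  labels <- c(rep(-1L, config$n_group_a), rep(1L, config$n_group_b))
  ids <- sprintf("subj_%03d", seq_len(n))
  d <- config$grid_shape

  volumes <- with_seed(config$seed, {
    lapply(seq_len(n), function(i) {
      v <- template + array(stats::rnorm(prod(d), sd = config$noise_sd), dim = d)
      if (labels[i] > 0) v <- v + effect
      v
    })
  })
  names(volumes) <- ids

  structure(
    list(
      volumes = volumes,
      labels = tibble::tibble(
        subject_id = ids,
        group = ifelse(labels < 0, "A", "B"),
        label = labels
      ),
      effect_mask = mask,
      voxel_size_mm = config$voxel_size_mm,
      config = config
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects (%d A / %d B), grid %s, voxel %s mm\n",
    length(x$volumes), x$config$n_group_a, x$config$n_group_b,
    paste(x$config$grid_shape, collapse = "x"),
    paste(x$voxel_size_mm, collapse = "x")
  ))
  cat(sprintf("  effect magnitude %g, noise sd %g, seed %d\n",
              x$config$effect_magnitude, x$config$noise_sd, x$config$seed))
  invisible(x)
}

#' Write a cohort to disk as NIfTI volumes plus a labels table
#'
#' Writes one uncompressed NIfTI-1 file per subject (voxel size on the
#' affine diagonal), the ground-truth effect mask as NIfTI, a tab-separated
#' labels table, and a JSON manifest listing every file written.
#'
#' @param cohort A `synthetic_cohort` (or compatible list).
#' @param directory Output directory; created if missing.
#' @return Invisibly, the manifest: a character vector of file paths
#'   (subject volumes, then labels table, then mask), also written to
#'   `manifest.json`.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stopf("cannot create directory '%s'", directory)

  paths <- character(0)
  for (id in names(cohort$volumes)) {
    p <- file.path(directory, paste0(id, ".nii"))
    write_volume(cohort$volumes[[id]], cohort$voxel_size_mm, p)
    paths <- c(paths, p)
  }
  labels_path <- file.path(directory, "labels.tsv")
  utils::write.table(cohort$labels[, c("subject_id", "label")], labels_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mask_path <- file.path(directory, "effect_mask.nii")
  write_volume(cohort$effect_mask, cohort$voxel_size_mm, mask_path)
  manifest <- c(paths, labels_path, mask_path)
  jsonlite::write_json(
    list(files = basename(manifest), n_subjects = length(cohort$volumes)),
    file.path(directory, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}

write_volume <- function(arr, voxel_size_mm, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Loads every subject NIfTI listed in the labels table, the effect mask if
#' present, and checks that all volumes share one grid and voxel size.
#' Volumes containing non-finite values are rejected at load.
#'
#' @param directory Directory containing `labels.tsv` and per-subject
#'   `.nii`/`.nii.gz` files named by subject id.
#' @return A `synthetic_cohort`-shaped list (with `config = NULL` for
#'   cohorts of external provenance).
#' @export
read_cohort <- function(directory) {
  labels_path <- file.path(directory, "labels.tsv")
  if (!file.exists(labels_path)) stopf("labels table not found: %s", labels_path)
  labels <- utils::read.table(labels_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  volumes <- list()
  voxel <- NULL
  shape <- NULL
  for (id in labels$subject_id) {
    p <- file.path(directory, paste0(id, ".nii"))
    if (!file.exists(p)) p <- file.path(directory, paste0(id, ".nii.gz"))
    if (!file.exists(p)) stopf("volume for subject '%s' not found in %s", id, directory)
    img <- RNifti::readNifti(p)
    arr <- array(as.numeric(img), dim = dim(img))
    if (any(!is.finite(arr))) stopf("volume '%s' contains non-finite values", id)
    vox <- RNifti::pixdim(img)
    if (is.null(shape)) {
      shape <- dim(arr)
      voxel <- vox
    } else {
      if (!identical(dim(arr), shape)) stopf("subject '%s' has mismatched grid shape", id)
    }
    volumes[[id]] <- arr
  }
  mask <- NULL
  mask_path <- file.path(directory, "effect_mask.nii")
  if (file.exists(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    mask <- array(as.numeric(m), dim = dim(m))
  }
  structure(
    list(
      volumes = volumes,
      labels = tibble::tibble(
        subject_id = labels$subject_id,
        group = ifelse(labels$label < 0, "A", "B"),
        label = as.integer(labels$label)
      ),
      effect_mask = mask,
      voxel_size_mm = as.numeric(voxel),
      config = NULL
    ),
    class = "synthetic_cohort"
  )
}
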