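# Small cohorts for fast tests. One spherical effect region in the upper
# octant of the grid, construction-time smoothing 8 mm at 4 mm voxels.
tiny_cohort <- function(n_a = 8, n_b = 8, grid = 16, effect = 0.2,
                        noise = 0.1, seed = 1L,
                        radius = max(3, grid %/% 4),
                        center = rep(round(grid * 0.6), 3)) {
  generate_cohort(cohort_config(
    n_group_a = n_a, n_group_b = n_b,
    grid_shape = rep(grid, 3L),
    voxel_size_mm = c(4, 4, 4),
    noise_sd = noise,
    effect_magnitude = effect,
    effect_regions = list(list(center = center, radius = radius)),
    smoothing_fwhm_mm = 8,
    seed = seed
  ))
}

# Smoothed + vectorized view of a cohort, the input to CV and maps.
tiny_fm <- function(cohort, fwhm = 8) {
  vectorize(smooth_cohort(cohort, fwhm))
}
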