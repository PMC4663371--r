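#' Declarative configuration for an end-to-end decoding run
#'
#' Collects every knob of the simulate / preprocess / cross-validate / map
#' pipeline in one validated object. Configs can also be loaded from a
#' YAML file with [load_pipeline_config()]; values passed here override
#' file values.
#'
#' @param cohort Either a [cohort_config()] (synthetic cohort) or a path
#'   to a directory readable by [read_cohort()].
#' @param smoothing_fwhm_mm Per-subject smoothing FWHM in mm (0 = none).
#' @param mask_strategy `"nonzero-any"` or `"all"`, see [build_mask()].
#' @param cv_schemes Integer vector of fold counts to evaluate (e.g.
#'   `c(20, 10)`).
#' @param cv_seed Seed for fold assignment.
#' @param cost SVM soft-margin cost.
#' @param k_range Coefficient counts, or `NULL` for the full usable range.
#' @param convention Metric convention, see [compute_metrics()].
#' @param map_k Coefficient count for the final maps (`NULL` = best k of
#'   the first CV scheme).
#' @param normalize_mode Map normalization mode, see [normalize_map()].
#' @param map_threshold Display threshold for the thresholded map.
#' @param output_dir Directory for all outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            smoothing_fwhm_mm = 8,
                            mask_strategy = "nonzero-any",
                            cv_schemes = c(20L, 10L),
                            cv_seed = 1L,
                            cost = 1,
                            k_range = NULL,
                            convention = "standard",
                            map_k = NULL,
                            normalize_mode = "abs-minmax",
                            map_threshold = 0.5,
                            output_dir = "morphodecode_run") {
  structure(
    list(
      cohort = cohort,
      smoothing_fwhm_mm = smoothing_fwhm_mm,
      mask_strategy = mask_strategy,
      cv_schemes = as.integer(cv_schemes),
      cv_seed = as.integer(cv_seed),
      cost = cost,
      k_range = k_range,
      convention = convention,
      map_k = map_k,
      normalize_mode = normalize_mode,
      map_threshold = map_threshold,
      output_dir = output_dir
    ),
    class = "pipeline_config"
  )
}

#' Validate a pipeline configuration
#'
#' Checks every field and returns all violations at once rather than
#' failing on the first.
#'
#' @param config A `pipeline_config`.
#' @return A character vector of violations; empty if the config is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (is.character(config$cohort)) {
    if (!dir.exists(config$cohort))
      add(sprintf("cohort: directory '%s' does not exist", config$cohort))
    else if (!file.exists(file.path(config$cohort, "labels.tsv")))
      add(sprintf("cohort: labels table missing at '%s'",
                  file.path(config$cohort, "labels.tsv")))
  } else if (inherits(config$cohort, "cohort_config")) {
    ok <- tryCatch({ validate_cohort_config(config$cohort); TRUE },
                   error = function(e) { add(paste0("cohort: ", conditionMessage(e))); FALSE })
  } else {
    add("cohort: must be a cohort_config or a directory path")
  }
  if (!is.numeric(config$smoothing_fwhm_mm) || any(config$smoothing_fwhm_mm < 0))
    add("smoothing_fwhm_mm: must be nonnegative")
  if (!config$mask_strategy %in% c("nonzero-any", "all"))
    add("mask_strategy: must be 'nonzero-any' or 'all'")
  if (length(config$cv_schemes) < 1L || any(config$cv_schemes < 2L))
    add("cv_schemes: need at least one scheme with >= 2 folds")
  if (!is.numeric(config$cost) || config$cost <= 0)
    add("cost: must be positive")
  if (!config$convention %in% c("standard", "as-printed"))
    add("convention: must be 'standard' or 'as-printed'")
  if (!config$normalize_mode %in% c("abs-minmax", "signed-minmax"))
    add("normalize_mode: must be 'abs-minmax' or 'signed-minmax'")
  if (!is.numeric(config$map_threshold) ||
      config$map_threshold < 0 || config$map_threshold > 1)
    add(sprintf("map_threshold: %s is outside [0, 1]",
                format(config$map_threshold)))
  v
}

#' Load a pipeline configuration from a YAML file
#'
#' The file may contain any [pipeline_config()] field; a `cohort` mapping
#' with cohort-generator fields is converted to a [cohort_config()], a
#' `cohort` string is kept as a directory path.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$cohort) && is.list(raw$cohort)) {
    if (!is.null(raw$cohort$effect_regions)) {
      raw$cohort$effect_regions <- lapply(raw$cohort$effect_regions, function(r)
        list(center = as.numeric(r$center), radius = as.numeric(r$radius)))
    }
    raw$cohort <- do.call(cohort_config, raw$cohort)
  }
  do.call(pipeline_config, raw)
}

#' Run the full decoding pipeline
#'
#' Executes simulate (or load) -> smooth -> mask -> vectorize ->
#' cross-validate (each configured scheme) -> final maps -> export. All
#' outputs are deterministic functions of the config, so rerunning with
#' the same config reproduces every file byte for byte.
#'
#' Outputs written to `output_dir`:
#' \itemize{
#'   \item `metrics_<s>fold.csv` — per-k pooled metric curves per scheme;
#'   \item `best.json` — the best (k, accuracy, specificity, sensitivity)
#'     triple per scheme;
#'   \item `weight_map.nii`, `activation_map.nii`,
#'     `activation_map_normalized.nii`, `activation_map_thresholded.nii`
#'     (+ JSON sidecars);
#'   \item `manifest.json` — config echo, seeds and package version.
#' }
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress progress messages?
#' @return Invisibly, a run report: list with `cv` (named list of
#'   `cv_result`s), `maps`, `files`, `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  violations <- validate_config(config)
  if (length(violations) > 0L)
    stopf("invalid pipeline config:\n  - %s", paste(violations, collapse = "\n  - "))
  say <- function(...) if (!quiet) message(sprintf(...))

  say("[cohort] %s", if (is.character(config$cohort)) "loading from disk"
      else "generating synthetic cohort")
  cohort <- if (is.character(config$cohort)) read_cohort(config$cohort)
            else generate_cohort(config$cohort)

  say("[preprocess] smoothing (FWHM %s mm), mask '%s', vectorizing",
      paste(config$smoothing_fwhm_mm, collapse = "x"), config$mask_strategy)
  if (any(config$smoothing_fwhm_mm > 0))
    cohort <- smooth_cohort(cohort, config$smoothing_fwhm_mm)
  fm <- vectorize(cohort, build_mask(cohort, config$mask_strategy))

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  cv_results <- list()
  for (s in config$cv_schemes) {
    say("[cv] %d-fold stratified cross-validation", s)
    res <- run_cv(fm, n_folds = s, k_range = config$k_range,
                  cost = config$cost, seed = config$cv_seed,
                  convention = config$convention)
    cv_results[[paste0(s, "fold")]] <- res
    p <- file.path(config$output_dir, sprintf("metrics_%dfold.csv", s))
    utils::write.csv(res$metrics[, c("k", "accuracy", "specificity", "sensitivity")],
                     p, row.names = FALSE)
    files <- c(files, p)
    say("[cv] best: k = %d, accuracy %.3f", res$best$k, res$best$accuracy)
  }

  best_json <- file.path(config$output_dir, "best.json")
  jsonlite::write_json(
    lapply(cv_results, function(r) as.list(r$best[, c("k", "accuracy",
                                                      "specificity", "sensitivity")])),
    best_json, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  files <- c(files, best_json)

  map_k <- config$map_k %||% cv_results[[1]]$best$k
  say("[maps] final model on the full cohort, k = %d", map_k)
  maps <- fit_pattern_maps(fm, k = map_k, cost = config$cost)
  norm <- normalize_map(maps$activation, config$normalize_mode)
  thr <- threshold_map(norm, config$map_threshold)
  for (item in list(list(maps$weight, "weight_map.nii"),
                    list(maps$activation, "activation_map.nii"),
                    list(norm, "activation_map_normalized.nii"),
                    list(thr, "activation_map_thresholded.nii"))) {
    p <- file.path(config$output_dir, item[[2]])
    write_map(item[[1]], p, cohort$voxel_size_mm)
    files <- c(files, p)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("morphodecode")),
    config = serialize_config(config),
    map_k = map_k,
    n_subjects = nrow(fm$values),
    n_features = ncol(fm$values)
  )
  mp <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, mp)
  say("[done] %d files in %s", length(files), config$output_dir)

  invisible(list(cv = cv_results, maps = maps, files = files, config = config))
}

# Config echo for the manifest: the scientific parameters only — the
# output location is where the run lives, not part of its provenance.
serialize_config <- function(config) {
  out <- unclass(config)
  out$output_dir <- NULL
  if (inherits(out$cohort, "cohort_config")) out$cohort <- unclass(out$cohort)
  out
}
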