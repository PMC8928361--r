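#' Run configuration
#'
#' One source of truth for every tunable of the pipeline. Defaults follow
#' the reference analysis: 32 gray levels for texture discretization,
#' nested 10-fold cross-validation repeated 20 times, two-sample t filter
#' at alpha = 0.05, LASSO penalty grid (0.05, 0.10, ..., 0.60), linear SVM
#' with C = 1, and 1000 label permutations.
#'
#' @param n_bins gray-level count for intensity discretization.
#' @param k_outer,k_inner outer / inner cross-validation fold counts (>= 2).
#' @param n_repeats number of repeats of the whole nested CV.
#' @param alpha t-test selection threshold (strict `p < alpha`).
#' @param lambda_grid strictly increasing LASSO penalty grid.
#' @param svm_C linear SVM cost parameter.
#' @param n_permutations label permutations for the significance test.
#' @param base_seed integer base seed; each repeat r uses `base_seed + r`.
#' @param min_region_voxels regions smaller than this are dropped from the
#'   feature space (texture matrices are meaningless on tiny supports).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(n_bins = 32L,
                       k_outer = 10L,
                       k_inner = 10L,
                       n_repeats = 20L,
                       alpha = 0.05,
                       lambda_grid = seq(0.05, 0.60, by = 0.05),
                       svm_C = 1.0,
                       n_permutations = 1000L,
                       base_seed = 20260921L,
                       min_region_voxels = 10L) {
  cfg <- list(n_bins = as.integer(n_bins), k_outer = as.integer(k_outer),
              k_inner = as.integer(k_inner), n_repeats = as.integer(n_repeats),
              alpha = as.numeric(alpha),
              lambda_grid = as.numeric(lambda_grid),
              svm_C = as.numeric(svm_C),
              n_permutations = as.integer(n_permutations),
              base_seed = as.integer(base_seed),
              min_region_voxels = as.integer(min_region_voxels))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (cfg$n_bins < 2L) af_stop("af_bad_config", "n_bins must be >= 2")
  if (cfg$k_outer < 2L || cfg$k_inner < 2L)
    af_stop("af_bad_config", "k_outer and k_inner must be >= 2")
  if (cfg$n_repeats < 1L) af_stop("af_bad_config", "n_repeats must be >= 1")
  if (!(cfg$alpha > 0 && cfg$alpha < 1))
    af_stop("af_bad_config", "alpha must lie in (0, 1)")
  if (length(cfg$lambda_grid) < 1L || any(diff(cfg$lambda_grid) <= 0) ||
      any(cfg$lambda_grid <= 0))
    af_stop("af_bad_config", "lambda_grid must be strictly increasing and positive")
  if (cfg$svm_C <= 0) af_stop("af_bad_config", "svm_C must be positive")
  if (cfg$n_permutations < 1L)
    af_stop("af_bad_config", "n_permutations must be >= 1")
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

#' Read / write a run configuration as YAML
#'
#' The YAML document mirrors the [run_config()] fields; missing fields
#' fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) af_stop("af_missing_file", "file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    af_stop("af_bad_config", "unknown config fields: %s",
            paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' @rdname read_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
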