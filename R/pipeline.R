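#' Desk-scale run configuration
#'
#' A configuration sized for interactive and continuous-integration runs:
#' nested 5-fold cross-validation repeated 5 times and 99 permutations,
#' with all statistical settings (t-filter, penalty grid, SVM cost)
#' unchanged from [run_config()].
#'
#' @param ... overrides passed to [run_config()].
#' @return a `run_config`.
#' @export
desk_config <- function(...) {
  defaults <- list(k_outer = 5L, k_inner = 5L, n_repeats = 5L,
                   n_permutations = 99L)
  do.call(run_config, modifyList(defaults, list(...)))
}

md5_of <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes simulate, extract, train, validate, permute and report in
#' order, writing every stage output to `out_dir` so any stage can be
#' rerun in isolation, and records a run manifest (config snapshot,
#' seeds, stage timings, output MD5 hashes, package version). All
#' deterministic outputs are a pure function of the configuration and
#' seeds.
#'
#' @param out_dir output directory.
#' @param config a [run_config()]; default [desk_config()].
#' @param shape,n_regions synthetic atlas grid and parcel count.
#' @param n_pd,n_hc group sizes for the primary cohort (the external
#'   validation cohort uses the same sizes).
#' @param effect_regions atlas labels receiving the injected group effect.
#' @param mean_shift injected PD mean shift in map units; the default is
#'   twice the background voxel SD.
#' @param rho_clinical target Spearman correlation between the first
#'   effect region's mean feature and the simulated clinical score.
#' @param perm_repeats nested-CV repeats used inside the permutation test
#'   (the permutation stage reruns the full pipeline per shuffle, so a
#'   single repeat keeps desk runs tractable; logged).
#' @return the run manifest, invisibly; all artifacts under `out_dir`.
#' @export
run_all <- function(out_dir, config = desk_config(),
                    shape = c(24L, 24L, 24L), n_regions = 30L,
                    n_pd = 30L, n_hc = 30L,
                    effect_regions = c(5L, 15L, 25L),
                    mean_shift = NULL, rho_clinical = 0.6,
                    perm_repeats = 1L) {
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("alffradiomics")),
                   config = unclass(config),
                   seeds = list(), stages = list(), timings = list())
  tic <- function() proc.time()[["elapsed"]]
  base_sd <- 0.2
  if (is.null(mean_shift)) mean_shift <- 2 * base_sd

  # -- simulate --------------------------------------------------------------
  t0 <- tic()
  atlas_seed <- derive_seed(config$base_seed, 1L)
  cohort_seed <- derive_seed(config$base_seed, 2L)
  val_seed <- derive_seed(config$base_seed, 3L)
  score_seed <- derive_seed(config$base_seed, 4L)
  manifest$seeds <- list(atlas = atlas_seed, primary_cohort = cohort_seed,
                         validation_cohort = val_seed, scores = score_seed)
  atlas <- make_atlas(shape, n_regions = n_regions,
                      min_region_voxels = config$min_region_voxels,
                      seed = atlas_seed)
  effects <- lapply(effect_regions, effect_spec, mean_shift = mean_shift)
  spec_primary <- cohort_spec(n_pd = n_pd, n_hc = n_hc, effects = effects,
                              base_sd = base_sd, seed = cohort_seed)
  spec_val <- cohort_spec(n_pd = n_pd, n_hc = n_hc, effects = effects,
                          base_sd = base_sd, seed = val_seed)
  primary <- simulate_cohort(atlas, spec_primary)
  validation <- simulate_cohort(atlas, spec_val)
  sim_dir <- file.path(out_dir, "cohort_primary")
  val_dir <- file.path(out_dir, "cohort_validation")
  write_cohort(primary, atlas, sim_dir)
  write_cohort(validation, atlas, val_dir)
  manifest$timings$simulate <- tic() - t0
  manifest$stages$simulate <- as.list(md5_of(c(
    file.path(sim_dir, "participants.csv"),
    file.path(sim_dir, "atlas.nii.gz"),
    file.path(val_dir, "participants.csv"))))

  # -- extract ---------------------------------------------------------------
  t0 <- tic()
  ft_primary <- build_feature_table(primary$volumes, atlas, primary$subjects,
                                    n_bins = config$n_bins,
                                    min_region_voxels = config$min_region_voxels)
  ft_val <- build_feature_table(validation$volumes, atlas,
                                validation$subjects,
                                n_bins = config$n_bins,
                                min_region_voxels = config$min_region_voxels)
  f_primary <- file.path(out_dir, "features_primary.csv")
  f_val <- file.path(out_dir, "features_validation.csv")
  write_feature_table(ft_primary, f_primary)
  write_feature_table(ft_val, f_val)
  manifest$timings$extract <- tic() - t0
  manifest$stages$extract <- as.list(md5_of(c(f_primary, f_val)))

  # clinical scores linked to the first effect region's mean feature
  drive_id <- make_feature_id(effect_regions[1], "Mean", "original")
  pd_ids <- primary$subjects$subject_id[primary$subjects$group == "PD"]
  subjects <- simulate_clinical_scores(
    primary$subjects, unclass(ft_primary)[pd_ids, drive_id],
    rho_target = rho_clinical, score_names = "HDRS17", seed = score_seed)
  write_subjects(subjects, file.path(out_dir, "subjects_primary.csv"))

  # -- train -----------------------------------------------------------------
  t0 <- tic()
  zs <- zscore_fit_apply(ft_primary)
  fit <- nested_cv(zs$table, subjects$group, config)
  modal <- select_modal_lambda(fit$fold_records)
  final <- finalize_model(zs$table, subjects$group, fit$fold_records, config)
  train_json <- file.path(out_dir, "train_results.json")
  jsonlite::write_json(list(
    summary = as.list(fit$summary),
    modal_lambda = modal,
    final_lambda = final$lambda,
    lambda_table = as.list(fit$lambda_table),
    final_features = final$features,
    final_weights = as.list(coef(final)),
    fold_records = lapply(fit$fold_records, function(r)
      r[c("repeat_index", "fold", "lambda", "selected", "test_subjects",
          "predicted", "truth")])),
    train_json, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  manifest$timings$train <- tic() - t0
  manifest$stages$train <- as.list(md5_of(train_json))

  # -- validate --------------------------------------------------------------
  t0 <- tic()
  zs_val <- zscore_fit_apply(ft_val)
  ext <- external_validate(final, zs_val$table, validation$subjects$group)
  val_json <- file.path(out_dir, "validation_results.json")
  jsonlite::write_json(as.list(ext), val_json, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  manifest$timings$validate <- tic() - t0
  manifest$stages$validate <- as.list(md5_of(val_json))

  # -- permute ---------------------------------------------------------------
  t0 <- tic()
  perm_cfg <- do.call(run_config, modifyList(unclass(config),
                                             list(n_repeats = perm_repeats)))
  af_log("permute", "permutation nested CV uses %d repeat(s)", perm_repeats)
  perm <- permutation_test(zs$table, subjects$group, perm_cfg,
                           n_perm = config$n_permutations,
                           stat_kind = "accuracy")
  perm_json <- file.path(out_dir, "permutation_results.json")
  jsonlite::write_json(list(N = perm$N, N_GP = perm$N_GP, p = perm$p,
                            observed = perm$observed,
                            stat_kind = perm$stat_kind),
                       perm_json, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  manifest$timings$permute <- tic() - t0
  manifest$stages$permute <- as.list(md5_of(perm_json))

  # -- report ----------------------------------------------------------------
  t0 <- tic()
  rep <- top_regions(fit$fold_records, k = 10L)
  corr <- correlate_clinical(ft_primary, subjects, rep)
  freq_csv <- file.path(out_dir, "region_frequency.csv")
  corr_csv <- file.path(out_dir, "correlations.csv")
  write.csv(data.frame(region = as.integer(names(rep$region_frequency)),
                       frequency = unname(rep$region_frequency)),
            freq_csv, row.names = FALSE)
  write.csv(corr, corr_csv, row.names = FALSE)
  report_json <- file.path(out_dir, "report.json")
  jsonlite::write_json(list(
    top_regions = rep$top_regions,
    features = rep$features,
    mean_weight_convention = "signed weights averaged over folds where the feature was selected",
    correlations = corr),
    report_json, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  manifest$timings$report <- tic() - t0
  manifest$stages$report <- as.list(md5_of(c(freq_csv, corr_csv, report_json)))

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  af_log("run_all", "complete: %s", out_dir)
  invisible(manifest)
}
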