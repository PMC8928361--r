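# Shared fixtures, generated once per test run and cached. Sizes follow
# the desk-scale study conditions: 24^3 grid, 30 regions, 30 PD + 30 HC.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  v <- get0(name, .fixture_cache)
  if (is.null(v)) {
    v <- builder()
    assign(name, v, .fixture_cache)
  }
  v
}

std_atlas <- function() {
  fixture("atlas", function()
    make_atlas(c(24, 24, 24), n_regions = 30, min_region_voxels = 10,
               seed = 101))
}

# Zero-effect cohort and its standardized feature table.
null_cohort <- function() {
  fixture("null_cohort", function() {
    atlas <- std_atlas()
    coh <- simulate_cohort(atlas, cohort_spec(n_pd = 30, n_hc = 30,
                                              seed = 202))
    ft <- build_feature_table(coh$volumes, atlas, coh$subjects)
    list(cohort = coh, features = ft, z = zscore_fit_apply(ft)$table,
         group = coh$subjects$group)
  })
}

EFFECT_REGIONS <- c(5L, 15L, 25L)

# Strong-effect cohort: mean shift of 2 * base_sd in 3 of 30 regions.
effect_cohort <- function(seed = 303) {
  key <- paste0("effect_cohort_", seed)
  fixture(key, function() {
    atlas <- std_atlas()
    eff <- lapply(EFFECT_REGIONS, effect_spec, mean_shift = 0.4)
    coh <- simulate_cohort(atlas, cohort_spec(n_pd = 30, n_hc = 30,
                                              effects = eff, base_sd = 0.2,
                                              seed = seed))
    ft <- build_feature_table(coh$volumes, atlas, coh$subjects)
    list(cohort = coh, features = ft, z = zscore_fit_apply(ft)$table,
         group = coh$subjects$group)
  })
}

# A small deterministic volume + one-region mask for feature unit tests.
tiny_pattern <- function() {
  arr <- array(0, c(3, 3, 1))
  arr[, , 1] <- matrix(c(1, 2, 1,
                         2, 3, 2,
                         1, 2, 1), 3, 3, byrow = TRUE)
  list(volume = brain_volume(arr, subject_id = "tiny"),
       mask = array(TRUE, c(3, 3, 1)))
}

random_feature_table <- function(n = 4L, regions = 1:2, seed = 7) {
  with_seed <- get("with_seed", asNamespace("alffradiomics"))
  with_seed(seed, {
    feats <- c("Mean", "Contrast", "SRE", "GLN", "Entropy")
    ids <- unlist(lapply(regions, function(r)
      make_feature_id(r, feats, "original")))
    m <- matrix(rnorm(n * length(ids)), n,
                dimnames = list(sprintf("S%02d", seq_len(n)), ids))
    feature_table(m)
  })
}
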