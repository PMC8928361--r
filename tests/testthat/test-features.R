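test_that("equal-width discretization follows the binning contract", {
  expect_identical(discretize(c(1, 1, 1), 32), rep(1L, 3))
  expect_identical(discretize(c(0, 1, 2, 3), 4), 1:4)
  expect_error(discretize(numeric(0), 4), class = "af_empty_region")
  expect_error(discretize(1:3, 1), class = "af_bad_config")
  # uniform values fill bins evenly (99% binomial band per bin)
  set.seed(42)
  v <- runif(6400)
  occ <- tabulate(discretize(v, 32), 32)
  expect_true(all(occ > 200 - 3 * sqrt(200)))
  expect_true(all(occ < 200 + 3 * sqrt(200)))
})

test_that("first-order features: degenerate and symmetric cases", {
  f <- first_order_features(c(5, 5, 5, 5))
  expect_equal(f[["Minimum"]], 5)
  expect_equal(f[["Maximum"]], 5)
  expect_equal(f[["Mean"]], 5)
  expect_equal(f[["Median"]], 5)
  expect_equal(f[["Range"]], 0)
  expect_equal(f[["Variance"]], 0)
  expect_equal(f[["Entropy"]], 0)
  expect_equal(f[["Uniformity"]], 1)
  g <- first_order_features(c(1, 2, 3, 4))
  expect_equal(g[["Mean"]], 2.5)
  expect_equal(g[["Median"]], 2.5)
  expect_equal(g[["Range"]], 3)
  expect_equal(g[["Skewness"]], 0)
  expect_length(f, 15L)
})

test_that("first-order features match the direct-formula oracle to 1e-10", {
  set.seed(11)
  for (rep in 1:5) {
    v <- rnorm(100)
    expect_equal(first_order_features(v, 32),
                 fo_oracle(v, 32), tolerance = 1e-10)
  }
})

test_that("co-occurrence matrix and features match exhaustive enumeration", {
  tp <- tiny_pattern()
  lev <- array(discretize(as.vector(tp$volume$data), 3), c(3, 3, 1))
  M <- glcm_matrix_oracle(lev, 3)
  # hand-counted sanity anchors on the 3x3 cross pattern
  expect_equal(sum(M), 2 * (12 + 8))       # 12 axial + 8 diagonal pairs
  got <- glcm_features(tp$volume, tp$mask, n_bins = 3)
  expect_equal(got, glcm_features_oracle(M), tolerance = 1e-10)
})

test_that("co-occurrence features match the oracle on random small images", {
  set.seed(5)
  for (rep in 1:6) {
    d <- sample(2:4, 3, replace = TRUE)
    arr <- array(sample(0:9, prod(d), replace = TRUE), d)
    vol <- brain_volume(arr)
    mask <- array(TRUE, d)
    nb <- 4
    lev <- array(discretize(as.vector(arr), nb), d)
    expect_equal(glcm_features(vol, mask, n_bins = nb),
                 glcm_features_oracle(glcm_matrix_oracle(lev, nb)),
                 tolerance = 1e-10)
  }
})

test_that("single-gray-level regions give the degenerate co-occurrence values", {
  vol <- brain_volume(array(7, c(3, 3, 3)))
  mask <- array(TRUE, c(3, 3, 3))
  f <- glcm_features(vol, mask, n_bins = 32)
  expect_equal(f[["Contrast"]], 0)
  expect_equal(f[["Homogeneity2"]], 1)
  expect_equal(f[["JointEntropy"]], 0)
  expect_equal(f[["MaximumProbability"]], 1)
  expect_equal(f[["Correlation"]], 0)   # zero-variance convention
  expect_equal(f[["IMC1"]], 0)
  expect_equal(f[["IMC2"]], 0)
})

test_that("feature name sets partition 15 + 22 + 11 and are disjoint", {
  nm <- feature_names()
  expect_length(nm, 48L)
  expect_identical(anyDuplicated(nm), 0L)
  f <- glcm_features(brain_volume(array(1:8, c(2, 2, 2))),
                     array(TRUE, c(2, 2, 2)), 4)
  g <- glrlm_features(brain_volume(array(1:8, c(2, 2, 2))),
                      array(TRUE, c(2, 2, 2)), 4)
  expect_length(f, 22L)
  expect_length(g, 11L)
  expect_length(intersect(names(f), names(g)), 0L)
})

test_that("run-length features: single straight run closed form", {
  # one straight line of 5 identical voxels: for the direction along the
  # line there is a single run of length 5 (SRE = 1/25, GLN = RLN = 1,
  # RP = 1/5); every other direction sees 5 runs of length 1
  arr <- array(0, c(5, 1, 1)); arr[] <- 3
  vol <- brain_volume(arr)
  mask <- array(TRUE, c(5, 1, 1))
  f <- glrlm_features(vol, mask, n_bins = 4)
  along <- c(SRE = 1 / 25, GLN = 1, RLN = 1, RP = 1 / 5)
  others <- c(SRE = 1, GLN = 5, RLN = 5, RP = 1)  # 5 runs of length 1
  for (nm in names(along)) {
    expected <- (along[[nm]] + 12 * others[[nm]]) / 13
    expect_equal(f[[nm]], expected, tolerance = 1e-12)
  }
})

test_that("run-length features match the run-enumeration oracle", {
  # alternating two-level 1D pattern: 6 runs of length 1 along the line
  arr <- array(rep(c(1, 2), 3), c(6, 1, 1))
  vol <- brain_volume(arr)
  mask <- array(TRUE, c(6, 1, 1))
  lev <- array(discretize(as.vector(arr), 2), c(6, 1, 1))
  expect_equal(glrlm_features(vol, mask, n_bins = 2),
               glrlm_oracle(lev, 2), tolerance = 1e-10)
  set.seed(6)
  for (rep in 1:6) {
    d <- sample(2:4, 3, replace = TRUE)
    arr <- array(sample(1:5, prod(d), replace = TRUE), d)
    nb <- 3
    lev <- array(discretize(as.vector(arr), nb), d)
    expect_equal(glrlm_features(brain_volume(arr), array(TRUE, d), nb),
                 glrlm_oracle(lev, nb), tolerance = 1e-10)
  }
})

test_that("region extraction yields 432 uniquely-keyed features", {
  atlas <- std_atlas()
  coh <- null_cohort()
  v <- extract_region_features(coh$cohort$volumes[[1]], atlas, 3)
  expect_length(v, 432L)
  expect_identical(anyDuplicated(names(v)), 0L)
  expect_false(any(is.na(v)))
  info <- parse_feature_id(names(v))
  expect_identical(unique(info$region), 3L)
  expect_identical(sort(unique(info$subband)),
                   sort(c("original", "LLL", "LLH", "LHL", "LHH",
                          "HLL", "HLH", "HHL", "HHH")))
  # count partition: 15 first-order + 33 texture per subband
  orig <- info$subband == "original"
  expect_identical(sum(orig), 48L)
  # determinism
  v2 <- extract_region_features(coh$cohort$volumes[[1]], atlas, 3)
  expect_identical(v, v2)
})

test_that("undersized regions are flagged missing and dropped from tables", {
  lab <- array(0L, c(8, 8, 8))
  lab[1:4, 1:4, 1:4] <- 1L
  lab[8, 8, 8] <- 2L          # 1 voxel < min_region_voxels
  atlas <- parcellation_atlas(lab)
  vol <- brain_volume(array(rnorm(512), c(8, 8, 8)), subject_id = "s1")
  v <- extract_region_features(vol, atlas, 2, min_region_voxels = 10)
  expect_true(all(is.na(v)))
  ft <- build_feature_table(list(s1 = vol), atlas, min_region_voxels = 10)
  expect_identical(attr(ft, "dropped_regions"), 2L)
  expect_identical(ncol(ft), 432L)   # only region 1 remains
  expect_false(any(parse_feature_id(colnames(ft))$region == 2L))
})

test_that("feature tables have deterministic column order and subject order", {
  coh <- null_cohort()
  ft <- coh$features
  expect_identical(ncol(ft), 30L * 432L)
  expect_identical(rownames(ft), coh$cohort$subjects$subject_id)
  info <- parse_feature_id(colnames(ft))
  expect_true(!is.unsorted(info$region))  # region ascending
  # within one region: subbands in fixed list order, features in fixed order
  first <- info[info$region == 1L, ]
  expect_identical(unique(first$subband),
                   c("original", "LLL", "LLH", "LHL", "LHH",
                     "HLL", "HLH", "HHL", "HHH"))
  expect_identical(first$feature[1:15],
                   feature_names()[1:15])
  expect_error(build_feature_table(coh$cohort$volumes[1:2],
                                   make_atlas(c(12, 12, 12), 2, seed = 1)),
               class = "af_grid_mismatch")
})

test_that("background intensities never influence a region's original-map features", {
  atlas <- std_atlas()
  coh <- null_cohort()
  vol <- coh$cohort$volumes[[2]]
  v1 <- extract_region_features(vol, atlas, 7)
  pert <- vol
  pert$data[atlas$labels != 7L] <- pert$data[atlas$labels != 7L] + 50
  v2 <- extract_region_features(pert, atlas, 7)
  orig_ids <- names(v1)[parse_feature_id(names(v1))$subband == "original"]
  expect_identical(v1[orig_ids], v2[orig_ids])
})
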