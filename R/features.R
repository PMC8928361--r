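# Canonical feature vocabulary: 15 first-order + 22 co-occurrence + 11
# run-length = 48 names per subband; with the original map and 8 wavelet
# subbands this gives 48 * 9 = 432 features per region.
FIRST_ORDER_NAMES <- c(
  "Minimum", "Maximum", "Mean", "Median", "Range", "Variance",
  "StandardDeviation", "Skewness", "Kurtosis", "Energy", "RootMeanSquare",
  "MeanAbsoluteDeviation", "Uniformity", "Entropy", "Percentile90")

GLCM_NAMES <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceEntropy", "Dissimilarity",
  "JointEnergy", "JointEntropy", "Homogeneity1", "Homogeneity2",
  "IMC1", "IMC2", "IDMN", "IDN", "InverseVariance", "MaximumProbability",
  "SumAverage", "SumEntropy", "SumVariance", "JointVariance")

GLRLM_NAMES <- c("SRE", "LRE", "GLN", "RLN", "RP",
                 "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE")

FEATURE_NAMES_48 <- c(FIRST_ORDER_NAMES, GLCM_NAMES, GLRLM_NAMES)

#' Canonical feature names
#'
#' @return character vector: 15 first-order, 22 gray-level co-occurrence
#'   and 11 run-length feature names (48 total per subband).
#' @export
feature_names <- function() FEATURE_NAMES_48

#' Equal-width gray-level discretization
#'
#' Bins span the `[min, max]` range of the supplied values; a constant
#' input maps every voxel to level 1.
#'
#' @param values nonempty finite numeric vector.
#' @param n_bins number of gray levels (>= 2).
#' @return integer levels in `1..n_bins`.
#' @export
discretize <- function(values, n_bins) {
  if (n_bins < 2L) af_stop("af_bad_config", "n_bins must be >= 2")
  if (length(values) == 0L) af_stop("af_empty_region", "empty input")
  if (any(!is.finite(values))) af_stop("af_nonfinite", "non-finite values")
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(rep(1L, length(values)))
  lev <- floor((values - lo) / (hi - lo) * n_bins) + 1L
  as.integer(pmin(lev, n_bins))
}

# 0 * log2(0) := 0
xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' First-order intensity histogram features
#'
#' The 15 first-order statistics of a region's intensity distribution.
#' Variance, standard deviation and the standardized moments use the
#' population (n) denominator; skewness and kurtosis of a constant region
#' are defined as 0. Entropy and uniformity are computed on the
#' equal-width discretized histogram.
#'
#' @param values nonempty numeric vector of region intensities.
#' @param n_bins gray levels for the entropy/uniformity histogram.
#' @return named numeric vector of length 15.
#' @export
first_order_features <- function(values, n_bins = 32L) {
  if (length(values) == 0L) af_stop("af_empty_region", "empty input")
  n <- length(values)
  mu <- mean(values)
  d <- values - mu
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  p <- tabulate(discretize(values, n_bins), nbins = n_bins) / n
  c(Minimum = min(values),
    Maximum = max(values),
    Mean = mu,
    Median = median(values),
    Range = max(values) - min(values),
    Variance = m2,
    StandardDeviation = sqrt(m2),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Energy = sum(values^2),
    RootMeanSquare = sqrt(mean(values^2)),
    MeanAbsoluteDeviation = mean(abs(d)),
    Uniformity = sum(p^2),
    Entropy = -sum(xlog2(p)),
    Percentile90 = unname(quantile(values, 0.9, type = 7)))
}

# ---- co-occurrence features ------------------------------------------------

# 22 co-occurrence features from a raw symmetric count matrix (already
# summed over directions). Degenerate cases: zero marginal variance gives
# Correlation = 0; zero marginal entropy gives IMC1 = IMC2 = 0.
glcm_feature_vector <- function(counts) {
  n_bins <- nrow(counts)
  v <- cpp_glcm_features(array(counts, c(n_bins, n_bins, 1L)), n_bins, 1L)
  stats::setNames(v[1, ], GLCM_NAMES)
}

# ---- run-length features ---------------------------------------------------

# 11 run-length features from an nbins x maxrun x 13 per-direction count
# array, each computed per direction and averaged over the 13 directions.
glrlm_feature_vector <- function(rl, n_voxels) {
  n_bins <- dim(rl)[1]; maxrun <- dim(rl)[2]
  v <- cpp_glrlm_features(array(rl, c(n_bins, maxrun, 13L, 1L)),
                          n_bins, maxrun, as.numeric(n_voxels), 1L)
  stats::setNames(v[1, ], GLRLM_NAMES)
}

# Per-region discretized level array (0 outside usable regions).
discretize_regions <- function(arr, labels, n_regions, n_bins) {
  lev <- cpp_discretize_regions(as.numeric(arr), as.integer(labels),
                                n_regions, n_bins)
  array(lev, dim = dim(arr))
}

# All-regions texture matrices for one (subband) array: returns a
# regions x 33 matrix of GLCM + GLRLM features.
texture_features_all <- function(arr, labels, n_regions, n_bins) {
  d <- dim(arr)
  lev <- discretize_regions(arr, labels, n_regions, n_bins)
  cc <- cpp_glcm_all(as.integer(lev), as.integer(labels),
                     d[1], d[2], d[3], n_bins, n_regions)
  maxrun <- max(d)
  rl <- cpp_glrlm_all(as.integer(lev), as.integer(labels),
                      d[1], d[2], d[3], n_bins, maxrun, n_regions)
  sizes <- tabulate(as.vector(labels), nbins = n_regions)
  out <- cbind(cpp_glcm_features(cc, n_bins, n_regions),
               cpp_glrlm_features(rl, n_bins, maxrun, as.numeric(sizes),
                                  n_regions))
  colnames(out) <- c(GLCM_NAMES, GLRLM_NAMES)
  out
}

#' Gray-level co-occurrence features of one region
#'
#' Builds the co-occurrence matrix at distance 1 over the 13 unique 3D
#' directions (symmetric accumulation, summed over directions, then
#' normalized) and returns the 22 classical features.
#'
#' @param volume a [brain_volume].
#' @param region_mask logical array of the volume's shape.
#' @param n_bins gray levels.
#' @return named numeric vector of 22 features.
#' @export
glcm_features <- function(volume, region_mask, n_bins = 32L) {
  stopifnot(inherits(volume, "brain_volume"),
            identical(dim(region_mask), dim(volume$data)))
  if (!any(region_mask)) af_stop("af_empty_region", "empty region mask")
  labels <- array(0L, dim(volume$data)); labels[region_mask] <- 1L
  d <- dim(volume$data)
  lev <- discretize_regions(volume$data, labels, 1L, n_bins)
  cc <- cpp_glcm_all(as.integer(lev), as.integer(labels),
                     d[1], d[2], d[3], n_bins, 1L)
  glcm_feature_vector(cc[, , 1])
}

#' Gray-level run-length features of one region
#'
#' Enumerates maximal same-level collinear voxel runs inside the region
#' along each of the 13 unique 3D directions and returns the 11 classical
#' run-length features, averaged over directions.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 11 features.
#' @export
glrlm_features <- function(volume, region_mask, n_bins = 32L) {
  stopifnot(inherits(volume, "brain_volume"),
            identical(dim(region_mask), dim(volume$data)))
  if (!any(region_mask)) af_stop("af_empty_region", "empty region mask")
  labels <- array(0L, dim(volume$data)); labels[region_mask] <- 1L
  d <- dim(volume$data)
  lev <- discretize_regions(volume$data, labels, 1L, n_bins)
  rl <- cpp_glrlm_all(as.integer(lev), as.integer(labels),
                      d[1], d[2], d[3], n_bins, max(d), 1L)
  glrlm_feature_vector(rl[, , , 1], sum(region_mask))
}

# The 9-array stack: original map plus the 8 stationary wavelet subbands.
subband_stack <- function(volume) {
  sb <- wavelet_subbands(volume)
  c(list(original = volume$data), lapply(sb, `[[`, "data"))
}

#' Extract the full multi-order feature set of one region
#'
#' 48 features (15 first-order + 22 co-occurrence + 11 run-length) on the
#' original map and on each of the 8 stationary wavelet subbands:
#' 48 x 9 = 432 features, keyed by serialized feature ids.
#'
#' @param volume a [brain_volume].
#' @param atlas a [parcellation_atlas] on the same grid.
#' @param region region label to extract.
#' @param n_bins gray levels for discretization (per region, per subband).
#' @param min_region_voxels regions smaller than this yield all-`NA`
#'   features (flagged missing).
#' @return named numeric vector of length 432.
#' @export
extract_region_features <- function(volume, atlas, region, n_bins = 32L,
                                    min_region_voxels = 10L) {
  stopifnot(inherits(volume, "brain_volume"),
            inherits(atlas, "parcellation_atlas"))
  if (!identical(dim(volume$data), dim(atlas$labels)))
    af_stop("af_grid_mismatch", "volume and atlas grids differ")
  region <- as.integer(region)
  if (region < 1L || region > atlas$n_regions)
    af_stop("af_bad_region", "region %d not in atlas", region)
  ids <- as.vector(t(outer(SUBBANDS, FEATURE_NAMES_48,
                           function(s, f) make_feature_id(region, f, s))))
  mask <- atlas$labels == region
  nv <- sum(mask)
  if (nv < min_region_voxels) {
    af_log("extract", "region %d has %d voxels < %d: flagged missing",
           region, nv, min_region_voxels)
    return(stats::setNames(rep(NA_real_, 432L), ids))
  }
  stack <- subband_stack(volume)
  out <- numeric(0)
  for (s in SUBBANDS) {
    arr <- stack[[s]]
    v <- arr[mask]
    labels <- array(0L, dim(arr)); labels[mask] <- 1L
    d <- dim(arr)
    lev <- discretize_regions(arr, labels, 1L, n_bins)
    cc <- cpp_glcm_all(as.integer(lev), as.integer(labels),
                       d[1], d[2], d[3], n_bins, 1L)
    rl <- cpp_glrlm_all(as.integer(lev), as.integer(labels),
                        d[1], d[2], d[3], n_bins, max(d), 1L)
    out <- c(out, first_order_features(v, n_bins),
             glcm_feature_vector(cc[, , 1]),
             glrlm_feature_vector(rl[, , , 1], nv))
  }
  stats::setNames(out, ids)
}

#' Build the cohort feature table
#'
#' Extracts all 432 features for every usable atlas region from every
#' subject volume. Regions smaller than `min_region_voxels` are dropped
#' consistently across subjects and recorded in the `dropped_regions`
#' attribute. Column order is deterministic: region ascending, subband in
#' the fixed list order, feature in the fixed list order.
#'
#' @param volumes list of [brain_volume] objects, one per subject; names
#'   (or `subject_id` fields) identify subjects.
#' @param atlas a [parcellation_atlas] on the volumes' grid.
#' @param subjects optional [subjects_table]; when given, rows follow its
#'   order and every subject must have a volume.
#' @param n_bins,min_region_voxels see [run_config()].
#' @return a [feature_table] with attribute `dropped_regions`.
#' @export
build_feature_table <- function(volumes, atlas, subjects = NULL,
                                n_bins = 32L, min_region_voxels = 10L) {
  stopifnot(inherits(atlas, "parcellation_atlas"))
  ids <- vapply(volumes, function(v) v$subject_id, "")
  if (!is.null(names(volumes)) && all(nzchar(names(volumes))))
    ids <- names(volumes)
  if (anyDuplicated(ids)) af_stop("af_bad_subjects", "duplicate subject ids")
  if (!is.null(subjects)) {
    missing <- setdiff(subjects$subject_id, ids)
    if (length(missing))
      af_stop("af_subject_mismatch", "subject %s has no volume", missing[1])
    volumes <- volumes[match(subjects$subject_id, ids)]
    ids <- subjects$subject_id
  }
  sizes <- region_sizes(atlas)
  keep <- which(sizes >= min_region_voxels)
  dropped <- which(sizes < min_region_voxels)
  if (length(dropped))
    af_log("extract", "dropping %d undersized regions: %s",
           length(dropped), paste(dropped, collapse = ","))
  if (!length(keep)) af_stop("af_bad_atlas", "no usable regions")
  cols <- unlist(lapply(keep, function(r)
    as.vector(t(outer(SUBBANDS, FEATURE_NAMES_48,
                      function(s, f) make_feature_id(r, f, s))))))
  labels <- atlas$labels
  labels[labels %in% dropped] <- 0L
  nreg <- atlas$n_regions
  X <- matrix(NA_real_, length(volumes), length(cols),
              dimnames = list(ids, cols))
  for (si in seq_along(volumes)) {
    vol <- volumes[[si]]
    if (!identical(dim(vol$data), dim(atlas$labels)))
      af_stop("af_grid_mismatch", "volume %s grid differs from atlas", ids[si])
    stack <- subband_stack(vol)
    blocks <- lapply(SUBBANDS, function(s) {
      arr <- stack[[s]]
      fo <- cpp_first_order_all(as.numeric(arr), as.integer(labels),
                                nreg, n_bins)
      colnames(fo) <- FIRST_ORDER_NAMES
      tx <- texture_features_all(arr, labels, nreg, n_bins)
      cbind(fo, tx)[keep, , drop = FALSE]
    })
    # rows are regions; flattening row-major gives region-major columns
    # with subband blocks in list order and features in canonical order
    X[si, ] <- as.vector(t(do.call(cbind, blocks)))
  }
  af_log("extract", "feature table %d subjects x %d columns (%d regions)",
         nrow(X), ncol(X), length(keep))
  ft <- feature_table(X)
  attr(ft, "dropped_regions") <- as.integer(dropped)
  ft
}
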