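#' Group-effect specification for the cohort simulator
#'
#' Describes one region-localized group difference injected into the PD
#' group: a shift of the regional mean intensity (in map units) and/or
#' extra voxel-wise noise (heteroscedasticity) that alters the region's
#' spatial heterogeneity — and hence its texture features — without moving
#' its mean.
#'
#' @param region atlas label (1..R).
#' @param mean_shift added to PD-group intensities in the region.
#' @param texture_shift extra voxel-wise noise SD in the PD group (>= 0).
#' @return a list of class `effect_spec`.
#' @export
effect_spec <- function(region, mean_shift = 0, texture_shift = 0) {
  if (texture_shift < 0) af_stop("af_bad_spec", "texture_shift must be >= 0")
  structure(list(region = as.integer(region),
                 mean_shift = as.numeric(mean_shift),
                 texture_shift = as.numeric(texture_shift)),
            class = "effect_spec")
}

#' Cohort specification for the simulator
#'
#' Defaults mirror the reference study conditions: 59 PD patients and 41
#' healthy controls, 3 mm isotropic voxels, 6 mm FWHM smoothing, and an
#' ALFF-like intensity scale (mean 1, voxel SD 0.2).
#'
#' @param n_pd,n_hc group sizes (each >= 2).
#' @param effects list of [effect_spec()] objects.
#' @param base_mean,base_sd background intensity model: each map is
#'   `base_mean + base_sd * (smoothed unit-variance Gaussian field)`.
#' @param smoothing_fwhm Gaussian smoothing FWHM in mm (>= 0).
#' @param spacing voxel size in mm (length 3).
#' @param seed RNG seed; every simulator output is a pure function of
#'   (spec, seed).
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pd = 59L, n_hc = 41L, effects = list(),
                        base_mean = 1.0, base_sd = 0.2,
                        smoothing_fwhm = 6.0, spacing = c(3, 3, 3),
                        seed = 1L) {
  if (n_pd < 2L || n_hc < 2L) af_stop("af_bad_spec", "need >= 2 per group")
  if (smoothing_fwhm < 0) af_stop("af_bad_spec", "smoothing_fwhm must be >= 0")
  stopifnot(all(vapply(effects, inherits, TRUE, "effect_spec")))
  structure(list(n_pd = as.integer(n_pd), n_hc = as.integer(n_hc),
                 effects = effects, base_mean = base_mean, base_sd = base_sd,
                 smoothing_fwhm = smoothing_fwhm,
                 spacing = as.numeric(spacing), seed = as.integer(seed)),
            class = "cohort_spec")
}

# 1D discrete Gaussian kernel for a given FWHM (mm) and spacing (mm).
gaussian_kernel <- function(fwhm, spacing) {
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / spacing
  if (sigma == 0) return(1)
  radius <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing with edge renormalization (each boundary
# row of the convolution matrix is rescaled to sum 1).
smooth_field <- function(arr, fwhm, spacing) {
  if (fwhm == 0) return(arr)
  d <- dim(arr)
  for (axis in 1:3) {
    k <- gaussian_kernel(fwhm, spacing[axis])
    if (length(k) == 1L) next
    n <- d[axis]
    radius <- (length(k) - 1L) / 2L
    K <- matrix(0, n, n)
    for (j in seq_along(k)) {
      off <- j - radius - 1L
      i <- seq_len(n)
      ok <- i + off >= 1L & i + off <= n
      K[cbind(i[ok], i[ok] + off)] <- k[j]
    }
    K <- K / rowSums(K)
    arr <- if (axis == 1L) {
      array(K %*% matrix(arr, d[1]), dim = d)
    } else if (axis == 2L) {
      aperm(array(K %*% matrix(aperm(arr, c(2, 1, 3)), d[2]),
                  dim = d[c(2, 1, 3)]), c(2, 1, 3))
    } else {
      aperm(array(K %*% matrix(aperm(arr, c(3, 1, 2)), d[3]),
                  dim = d[c(3, 1, 2)]), c(2, 3, 1))
    }
  }
  arr
}

# Variance attenuation of interior voxels under separable smoothing,
# used to rescale the smoothed field back to (approximately) unit SD.
smoothing_var_factor <- function(fwhm, spacing) {
  prod(vapply(1:3, function(a) sum(gaussian_kernel(fwhm, spacing[a])^2), 0.0))
}

#' Generate a synthetic parcellation atlas
#'
#' Carves an ellipsoidal "brain" mask inside the grid and partitions it
#' into contiguous regions by seeded Voronoi growth: region seeds are
#' sampled uniformly from the mask and grown by multi-source breadth-first
#' search over 6-connected neighbors. If any region ends up smaller than
#' `min_region_voxels`, new seeds are drawn (deterministically from the
#' same seed stream, up to 25 attempts).
#'
#' @param shape integer length-3 grid dimensions.
#' @param n_regions number of regions; the default mirrors the 246-parcel
#'   whole-brain atlas used with real data.
#' @param min_region_voxels minimum voxels per region.
#' @param seed RNG seed; output is deterministic given the arguments.
#' @return a [parcellation_atlas].
#' @export
make_atlas <- function(shape, n_regions = 246L, min_region_voxels = 10L,
                       seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 3L))
  n_regions <- as.integer(n_regions)
  centre <- (shape + 1) / 2
  semi <- pmax(shape * 0.45, 1)
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  inmask <- ((g$x - centre[1]) / semi[1])^2 + ((g$y - centre[2]) / semi[2])^2 +
    ((g$z - centre[3]) / semi[3])^2 <= 1
  mask_idx <- which(inmask)
  if (length(mask_idx) < n_regions * min_region_voxels)
    af_stop("af_infeasible_atlas",
            "mask has %d voxels; cannot host %d regions of >= %d voxels",
            length(mask_idx), n_regions, min_region_voxels)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  mask <- array(FALSE, shape); mask[mask_idx] <- TRUE
  labels <- with_seed(seed, {
    lab <- NULL
    for (attempt in seq_len(25L)) {
      seeds <- sample(mask_idx, n_regions)
      lab_try <- grow_regions(mask, seeds, shape)
      if (min(tabulate(lab_try[lab_try > 0L], n_regions)) >= min_region_voxels) {
        lab <- lab_try
        break
      }
    }
    lab
  })
  if (is.null(labels))
    af_stop("af_infeasible_atlas",
            "could not grow %d regions of >= %d voxels in the mask",
            n_regions, min_region_voxels)
  af_log("atlas", "seed=%d shape=%s regions=%d mask=%d voxels",
         seed, paste(shape, collapse = "x"), n_regions, length(mask_idx))
  parcellation_atlas(labels)
}

# Multi-source BFS Voronoi growth over the 6-neighborhood.
grow_regions <- function(mask, seeds, shape) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  labels <- array(0L, shape)
  labels[seeds] <- seq_along(seeds)
  queue <- seeds
  qhead <- 1L
  nxy <- nx * ny
  while (qhead <= length(queue)) {
    v <- queue[qhead]; qhead <- qhead + 1L
    l <- labels[v]
    v0 <- v - 1L
    x <- v0 %% nx; y <- (v0 %/% nx) %% ny; z <- v0 %/% nxy
    nb <- c(if (x > 0L) v - 1L, if (x < nx - 1L) v + 1L,
            if (y > 0L) v - nx, if (y < ny - 1L) v + nx,
            if (z > 0L) v - nxy, if (z < nz - 1L) v + nxy)
    nb <- nb[mask[nb] & labels[nb] == 0L]
    if (length(nb)) {
      labels[nb] <- l
      queue <- c(queue, nb)
    }
  }
  labels
}

#' Simulate an ALFF-like cohort
#'
#' Each subject map is a Gaussian white-noise field smoothed to the
#' specified FWHM (rescaled so interior voxel SD is `base_sd`) on top of
#' `base_mean`. Values outside the atlas mask are set to 0. For PD
#' subjects each [effect_spec()] adds `mean_shift` to its region and
#' injects extra unsmoothed voxel noise with SD `texture_shift` there.
#'
#' @param atlas a [parcellation_atlas].
#' @param spec a [cohort_spec()].
#' @return list with `volumes` (named list of [brain_volume]) and
#'   `subjects` (a [subjects_table]).
#' @export
simulate_cohort <- function(atlas, spec) {
  stopifnot(inherits(atlas, "parcellation_atlas"),
            inherits(spec, "cohort_spec"))
  for (e in spec$effects)
    if (e$region < 1L || e$region > atlas$n_regions)
      af_stop("af_bad_spec", "effect region %d absent from atlas", e$region)
  shape <- dim(atlas$labels)
  inmask <- atlas$labels > 0L
  ids <- c(sprintf("PD%03d", seq_len(spec$n_pd)),
           sprintf("HC%03d", seq_len(spec$n_hc)))
  groups <- rep(c("PD", "HC"), c(spec$n_pd, spec$n_hc))
  sdfac <- sqrt(smoothing_var_factor(spec$smoothing_fwhm, spec$spacing))
  volumes <- with_seed(spec$seed, {
    lapply(seq_along(ids), function(i) {
      field <- array(rnorm(prod(shape)), shape)
      field <- smooth_field(field, spec$smoothing_fwhm, spec$spacing) / sdfac
      arr <- spec$base_mean + spec$base_sd * field
      if (groups[i] == "PD") {
        for (e in spec$effects) {
          idx <- which(atlas$labels == e$region)
          arr[idx] <- arr[idx] + e$mean_shift
          if (e$texture_shift > 0)
            arr[idx] <- arr[idx] + rnorm(length(idx), 0, e$texture_shift)
        }
      }
      arr[!inmask] <- 0
      brain_volume(arr, spacing = spec$spacing, subject_id = ids[i])
    })
  })
  names(volumes) <- ids
  af_log("simulate", "seed=%d cohort %d PD + %d HC on %s grid",
         spec$seed, spec$n_pd, spec$n_hc, paste(shape, collapse = "x"))
  list(volumes = volumes, subjects = subjects_table(ids, groups))
}

#' Simulate clinical scores linked to a regional feature
#'
#' Generates, for the PD subjects, a clinical score monotonically linked
#' to a chosen feature through a Gaussian copula: the score's latent value
#' is `rho_p * z + sqrt(1 - rho_p^2) * noise`, where `z` is the normal
#' score of the feature's rank and `rho_p = 2 sin(pi * rho_target / 6)` is
#' the Pearson correlation that yields a Spearman correlation of
#' approximately `rho_target` under bivariate normality. For
#' `|rho_target| >= 0.99` the score is an exact monotone transform of the
#' feature (no noise). Scores for measures listed in `hc_measures`
#' (collected in both groups, e.g. MMSE) are drawn independently for HC
#' subjects; all other measures stay `NA` for HC.
#'
#' @param subjects a [subjects_table].
#' @param feature_values numeric vector named by PD subject ids (or in PD
#'   row order), the feature driving the score.
#' @param rho_target target Spearman correlation, in (-1, 1) or +/-0.99+
#'   for the exact monotone case.
#' @param score_names names of the score columns to create.
#' @param seed RNG seed.
#' @param hc_measures measures also collected in HC subjects.
#' @return the [subjects_table] with the new score columns appended.
#' @export
simulate_clinical_scores <- function(subjects, feature_values, rho_target,
                                     score_names = "HDRS17", seed = 1L,
                                     hc_measures = "MMSE") {
  stopifnot(inherits(subjects, "subjects_table"))
  if (abs(rho_target) >= 1)
    af_stop("af_bad_spec", "rho_target must lie in (-1, 1)")
  pd <- which(subjects$group == "PD")
  if (!is.null(names(feature_values)))
    feature_values <- feature_values[subjects$subject_id[pd]]
  if (length(feature_values) != length(pd) || any(is.na(feature_values)))
    af_stop("af_bad_spec", "feature_values must align with the PD subjects")
  n <- length(pd)
  z <- qnorm((rank(feature_values, ties.method = "average") - 0.5) / n)
  rho_p <- 2 * sin(pi * rho_target / 6)
  with_seed(seed, {
    for (nm in score_names) {
      latent <- if (abs(rho_target) >= 0.99) sign(rho_target) * z
      else rho_p * z + sqrt(1 - rho_p^2) * rnorm(n)
      col <- rep(NA_real_, nrow(subjects))
      col[pd] <- 10 + 5 * latent
      if (nm %in% hc_measures) {
        hc <- which(subjects$group == "HC")
        col[hc] <- 10 + 5 * rnorm(length(hc))
      }
      subjects[[nm]] <- col
    }
  })
  af_log("simulate", "scores %s for %d PD subjects at rho_target=%.2f",
         paste(score_names, collapse = ","), n, rho_target)
  subjects
}

#' Write a simulated cohort in the standard layout
#'
#' One NIfTI per subject, one atlas NIfTI and one participants CSV.
#'
#' @param cohort result of [simulate_cohort()].
#' @param atlas the [parcellation_atlas] used.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (v in cohort$volumes)
    write_volume(v, file.path(dir, paste0(v$subject_id, ".nii.gz")))
  write_atlas(atlas, file.path(dir, "atlas.nii.gz"))
  write_subjects(cohort$subjects, file.path(dir, "participants.csv"))
  invisible(dir)
}
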