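#' Brain volume objects
#'
#' A `brain_volume` holds one subject's 3D scalar map (for example an ALFF
#' map) together with its voxel spacing (mm) and 4x4 voxel-to-world affine.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3 voxel size in mm, strictly positive.
#' @param affine 4x4 voxel-to-world transform; default is a diagonal
#'   scaling by `spacing`.
#' @param subject_id optional subject identifier.
#' @return An object of class `brain_volume`.
#' @export
brain_volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                         subject_id = NA_character_) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    af_stop("af_non_3d", "non-3D image: got %d dimensions", length(dim(data)))
  if (any(dim(data) < 1L)) af_stop("af_bad_volume", "empty dimension")
  data <- array(as.numeric(data), dim = dim(data))  # plain array, no attrs
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    af_stop("af_bad_volume", "spacing must be 3 strictly positive values")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    af_stop("af_bad_volume", "affine must be 4x4")
  structure(list(data = data, spacing = spacing, affine = affine,
                 subject_id = as.character(subject_id)),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat(sprintf("<brain_volume> %s  dims %s  spacing %s mm\n",
              x$subject_id, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @export
dim.brain_volume <- function(x) dim(x$data)

#' Parcellation atlas objects
#'
#' An integer label volume aligned to the data grid: 0 is background and
#' labels 1..R index regions. Every label in 1..R must occur at least once.
#'
#' @param labels integer 3D array of region labels.
#' @param region_names optional character vector naming labels 1..R.
#' @return An object of class `parcellation_atlas` with element
#'   `n_regions` = R (the maximum label).
#' @export
parcellation_atlas <- function(labels, region_names = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    af_stop("af_non_3d", "non-3D image: got %d dimensions", length(dim(labels)))
  labels <- array(as.vector(labels), dim = dim(labels))  # strip attributes
  lv <- as.vector(labels)
  if (any(!is.finite(lv))) af_stop("af_bad_atlas", "non-finite labels")
  if (max(abs(lv - round(lv))) > 1e-6)
    af_stop("af_non_integer_atlas", "atlas has non-integer values beyond tolerance 1e-6")
  labels <- array(as.integer(round(lv)), dim = dim(labels))
  if (min(labels) < 0L) af_stop("af_bad_atlas", "negative labels")
  r <- max(labels)
  if (r < 1L) af_stop("af_empty_atlas", "no labeled regions")
  present <- tabulate(as.vector(labels), nbins = r) > 0L
  if (!all(present))
    af_stop("af_missing_label", "missing label %d", which(!present)[1])
  if (!is.null(region_names) && length(region_names) != r)
    af_stop("af_bad_atlas", "region_names must have length n_regions")
  structure(list(labels = labels, n_regions = as.integer(r),
                 region_names = region_names),
            class = "parcellation_atlas")
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  cat(sprintf("<parcellation_atlas> %d regions  dims %s  (%d in-mask voxels)\n",
              x$n_regions, paste(dim(x$labels), collapse = "x"),
              sum(x$labels > 0L)))
  invisible(x)
}

#' @export
dim.parcellation_atlas <- function(x) dim(x$labels)

#' Region voxel counts
#'
#' @param atlas a `parcellation_atlas`.
#' @return integer vector of length `n_regions` with voxels per label.
#' @export
region_sizes <- function(atlas) {
  stopifnot(inherits(atlas, "parcellation_atlas"))
  tabulate(as.vector(atlas$labels), nbins = atlas$n_regions)
}

#' Read a 3D NIfTI volume
#'
#' @param path a readable `.nii` / `.nii.gz` file.
#' @param subject_id optional subject id attached to the volume; defaults
#'   to the file stem.
#' @return a [brain_volume].
#' @export
read_volume <- function(path, subject_id = NULL) {
  if (!file.exists(path)) af_stop("af_missing_file", "file not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) af_stop("af_unreadable_header",
                                              "unreadable NIfTI: %s (%s)",
                                              path, conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L)
    af_stop("af_non_3d", "non-3D image: %s has %d dimensions",
            path, length(dim(arr)))
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  sp <- RNifti::pixdim(img)[seq_len(3)]
  brain_volume(arr, spacing = sp, affine = RNifti::xform(img),
               subject_id = subject_id)
}

#' Write a brain volume as NIfTI
#'
#' @param volume a [brain_volume].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "brain_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read an integer parcellation atlas from NIfTI
#'
#' Values must be integer up to a tolerance of 1e-6; the number of regions
#' is the maximum label and every label 1..R must be present.
#'
#' @param path a readable NIfTI label map.
#' @param region_names optional label names.
#' @return a [parcellation_atlas].
#' @export
read_atlas <- function(path, region_names = NULL) {
  vol <- read_volume(path)
  parcellation_atlas(vol$data, region_names = region_names)
}

#' Write a parcellation atlas as NIfTI
#'
#' @param atlas a [parcellation_atlas].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "parcellation_atlas"))
  img <- RNifti::asNifti(atlas$labels)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}
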