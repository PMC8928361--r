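# Canonical feature-space vocabulary. Subband "original" denotes the
# unfiltered map; the eight wavelet subbands follow the axis order of the
# low/high-pass filter applied along (x, y, z).
SUBBANDS <- c("original", "LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

#' Serialize a feature identifier
#'
#' A feature is keyed by (region, feature name, subband) and serialized as
#' `"R{region:03d}|{feature}|{subband}"`, e.g. `"R007|Contrast|LHH"`.
#'
#' @param region integer region label(s).
#' @param feature feature name(s).
#' @param subband subband name(s), one of `"original"`, `"LLL"` .. `"HHH"`.
#' @return character vector of feature ids.
#' @export
make_feature_id <- function(region, feature, subband) {
  stopifnot(all(subband %in% SUBBANDS))
  sprintf("R%03d|%s|%s", as.integer(region), feature, subband)
}

#' Parse feature identifiers
#'
#' @param id character vector of serialized feature ids.
#' @return data.frame with columns `region` (integer), `feature`, `subband`.
#' @export
parse_feature_id <- function(id) {
  parts <- strsplit(id, "|", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    af_stop("af_bad_feature_id", "malformed feature id: %s",
            id[lengths(parts) != 3L][1])
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  if (!all(grepl("^R[0-9]{3,}$", m[, 1])))
    af_stop("af_bad_feature_id", "malformed region field in feature id")
  if (!all(m[, 3] %in% SUBBANDS))
    af_stop("af_bad_feature_id", "unknown subband in feature id")
  data.frame(region = as.integer(sub("^R", "", m[, 1])),
             feature = m[, 2], subband = m[, 3],
             stringsAsFactors = FALSE)
}

#' Construct a feature table
#'
#' Subjects x features numeric matrix keyed by serialized feature ids
#' (columns) and subject ids (rows).
#'
#' @param x numeric matrix with rownames = subject ids and colnames =
#'   feature ids.
#' @return the matrix with class `feature_table`.
#' @export
feature_table <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L) af_stop("af_empty_table", "empty feature table")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    af_stop("af_bad_table", "subject ids must be present and unique")
  if (is.null(colnames(x))) af_stop("af_bad_table", "feature ids missing")
  if (anyDuplicated(colnames(x)))
    af_stop("af_duplicate_feature", "duplicated FeatureID columns: %s",
            colnames(x)[duplicated(colnames(x))][1])
  parse_feature_id(colnames(x))  # validates id syntax
  storage.mode(x) <- "double"
  class(x) <- c("feature_table", class(x))
  x
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Write / read a feature table as CSV
#'
#' UTF-8 CSV, one header row of serialized feature ids, first column
#' `subject_id`. The round trip is lossless to full double precision.
#'
#' @param table a [feature_table].
#' @param path CSV path.
#' @return `write_feature_table`: `path` invisibly; `read_feature_table`:
#'   a [feature_table].
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(subject_id = rownames(table), check.names = FALSE)
  df <- cbind(df, as.data.frame(unclass(table), check.names = FALSE,
                                optional = TRUE))
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) af_stop("af_missing_file", "file not found: %s", path)
  df <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                 colClasses = NA)
  if (!"subject_id" %in% names(df))
    af_stop("af_bad_table", "feature CSV lacks subject_id column")
  m <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  rownames(m) <- as.character(df$subject_id)
  feature_table(m)
}

#' Construct a subjects table
#'
#' @param subject_id unique subject identifiers.
#' @param group group labels, `"PD"` or `"HC"`.
#' @param ... optional named clinical score vectors (may contain `NA`).
#' @return data.frame of class `subjects_table`.
#' @export
subjects_table <- function(subject_id, group, ...) {
  subject_id <- as.character(subject_id)
  group <- as.character(group)
  if (anyDuplicated(subject_id))
    af_stop("af_bad_subjects", "duplicate subject ids")
  if (length(group) != length(subject_id) || any(is.na(group) | group == ""))
    af_stop("af_bad_subjects", "group labels must be nonempty")
  if (!all(group %in% c("PD", "HC")))
    af_stop("af_bad_subjects", "group must be PD or HC")
  df <- data.frame(subject_id = subject_id, group = group,
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- as.numeric(extra[[nm]])
  class(df) <- c("subjects_table", "data.frame")
  df
}

#' Read / write a subjects table CSV
#'
#' @param path CSV with columns `subject_id`, `group` and optional numeric
#'   clinical-score columns.
#' @return a [subjects_table].
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) af_stop("af_missing_file", "file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("subject_id", "group") %in% names(df)))
    af_stop("af_bad_subjects", "subjects CSV needs subject_id and group columns")
  scores <- df[setdiff(names(df), c("subject_id", "group"))]
  do.call(subjects_table, c(list(subject_id = df$subject_id, group = df$group),
                            as.list(scores)))
}

#' @rdname read_subjects
#' @param subjects a [subjects_table].
#' @export
write_subjects <- function(subjects, path) {
  write.csv(as.data.frame(subjects), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

# Align a feature table's rows with a subjects table; error on mismatch.
align_subjects <- function(table, subjects) {
  if (!setequal(rownames(table), subjects$subject_id))
    af_stop("af_subject_mismatch",
            "subject ids in feature table and subjects table differ")
  table[match(subjects$subject_id, rownames(table)), , drop = FALSE]
}
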