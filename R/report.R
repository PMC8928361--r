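#' Selection frequencies across cross-validation folds
#'
#' A region's frequency is the fraction of outer folds (over all repeats)
#' in which at least one of its features entered that fold's final SVM; a
#' feature's frequency is the fraction of folds selecting that feature.
#' Only outer-fold final selections count, not inner-CV trial selections.
#'
#' @param fold_records `fold_records` from a [nested_cv()] fit.
#' @return list with `region` (named numeric, by region label) and
#'   `feature` (named numeric, by feature id).
#' @export
region_selection_frequency <- function(fold_records) {
  if (!length(fold_records)) af_stop("af_bad_input", "no fold records")
  n <- length(fold_records)
  feat_counts <- table(unlist(lapply(fold_records, `[[`, "selected")))
  reg_counts <- table(unlist(lapply(fold_records, function(rec) {
    if (!length(rec$selected)) return(integer(0))
    unique(parse_feature_id(rec$selected)$region)
  })))
  list(region = stats::setNames(as.numeric(reg_counts) / n,
                                names(reg_counts)),
       feature = stats::setNames(as.numeric(feat_counts) / n,
                                 names(feat_counts)))
}

#' Top discriminative regions and their features
#'
#' Ranks regions by selection frequency and keeps the top `k` (default
#' 10); ties at the cut go to the lower region label, so the report is
#' stable across reruns. The discriminative features are the selected
#' features belonging to those regions, each with its selection frequency
#' and its mean signed SVM weight over the folds that selected it (the
#' larger the absolute weight, the larger the contribution).
#'
#' @param fold_records `fold_records` from a [nested_cv()] fit.
#' @param k number of regions to keep; if fewer regions were ever
#'   selected, all of them are returned with a log note.
#' @return list of class `discriminative_report`: `region_frequency`
#'   (all regions), `top_regions` (data.frame region/frequency) and
#'   `features` (data.frame feature_id/region/frequency/mean_weight).
#' @export
top_regions <- function(fold_records, k = 10L) {
  freq <- region_selection_frequency(fold_records)
  rf <- freq$region
  regs <- as.integer(names(rf))
  ord <- order(-rf, regs)               # frequency desc, label asc on ties
  if (length(ord) < k) {
    af_log("report", "only %d regions ever selected (< k = %d)",
           length(ord), k)
    k <- length(ord)
  }
  top <- regs[ord[seq_len(k)]]
  top_df <- data.frame(region = top, frequency = unname(rf[ord[seq_len(k)]]))
  # mean signed weight over folds where the feature was selected
  wsum <- new.env(parent = emptyenv())
  for (rec in fold_records) {
    for (fid in rec$selected) {
      prev <- get0(fid, wsum, ifnotfound = c(0, 0))
      assign(fid, prev + c(rec$weights[[fid]], 1), wsum)
    }
  }
  fids <- names(freq$feature)
  info <- parse_feature_id(fids)
  in_top <- info$region %in% top
  mean_w <- vapply(fids[in_top], function(fid) {
    v <- get(fid, wsum); v[1] / v[2]
  }, 0.0)
  feats <- data.frame(feature_id = fids[in_top],
                      region = info$region[in_top],
                      frequency = unname(freq$feature[in_top]),
                      mean_weight = unname(mean_w),
                      stringsAsFactors = FALSE)
  feats <- feats[order(-feats$frequency, feats$feature_id), ]
  rownames(feats) <- NULL
  structure(list(region_frequency = rf, top_regions = top_df,
                 features = feats, k = k),
            class = "discriminative_report")
}

#' @export
print.discriminative_report <- function(x, ...) {
  cat(sprintf("<discriminative_report> top %d regions, %d discriminative features\n",
              nrow(x$top_regions), nrow(x$features)))
  print(head(x$top_regions, 10))
  invisible(x)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Rank correlation with average ranks for ties; the two-sided p-value
#' uses the t-approximation. Pairs with a missing value in either vector
#' are dropped; no multiplicity correction is applied.
#'
#' @param x,y numeric vectors of equal length (>= 4 complete pairs).
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) af_stop("af_bad_input", "need >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    af_stop("af_degenerate", "constant input: rank correlation undefined")
  rho <- cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Correlate discriminative features with clinical scores
#'
#' Computes Spearman correlations between every discriminative feature and
#' every clinical measure, within PD subjects only (matching the per-set
#' clinical collection of the reference analysis).
#'
#' @param table the (unstandardized or standardized) feature matrix —
#'   rank correlations are invariant to the per-column affine z-score.
#' @param subjects a [subjects_table] with clinical score columns.
#' @param report a [top_regions()] result (or character vector of feature
#'   ids).
#' @param measures clinical columns to use; default: every numeric column.
#' @return data.frame with feature_id, measure, rho, p, n.
#' @export
correlate_clinical <- function(table, subjects, report,
                               measures = NULL) {
  fids <- if (inherits(report, "discriminative_report"))
    report$features$feature_id else as.character(report)
  if (is.null(measures))
    measures <- setdiff(names(subjects)[vapply(subjects, is.numeric, TRUE)],
                        c("subject_id", "group"))
  pd <- subjects$subject_id[subjects$group == "PD"]
  pd <- intersect(pd, rownames(table))
  out <- NULL
  for (fid in fids) {
    fx <- unclass(table)[pd, fid]
    for (m in measures) {
      sy <- subjects[[m]][match(pd, subjects$subject_id)]
      ok <- is.finite(fx) & is.finite(sy)
      if (sum(ok) < 4L) next
      r <- spearman_correlation(fx[ok], sy[ok])
      out <- rbind(out, data.frame(feature_id = fid, measure = m,
                                   rho = r$rho, p = r$p, n = r$n,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(feature_id = character(0), measure = character(0),
                      rho = numeric(0), p = numeric(0), n = integer(0))
  out
}
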