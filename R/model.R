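# ---- standardization -------------------------------------------------------

#' Per-set z-score standardization
#'
#' Standardizes every feature column to mean 0 and SD 1 using the
#' population (n) denominator. Constant (zero-variance) columns are
#' dropped with a logged warning. The primary and any external validation
#' set must each be standardized independently with their own statistics.
#'
#' @param table numeric subjects x features matrix (>= 2 subjects).
#' @return list with `table` (standardized), `center`, `scale` (named per
#'   retained column) and `dropped` (constant columns).
#' @export
zscore_fit_apply <- function(table) {
  x <- unclass(table)
  if (nrow(x) < 2L) af_stop("af_bad_table", "need >= 2 subjects to standardize")
  ctr <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2L, ctr)^2))
  dropped <- colnames(x)[sdv == 0 | !is.finite(sdv)]
  if (length(dropped))
    af_log("zscore", "dropping %d constant columns", length(dropped))
  keep <- setdiff(colnames(x), dropped)
  z <- sweep(sweep(x[, keep, drop = FALSE], 2L, ctr[keep]), 2L, sdv[keep], "/")
  list(table = z, center = ctr[keep], scale = sdv[keep], dropped = dropped)
}

# ---- univariate filter -----------------------------------------------------

#' Two-sample t-test feature filter
#'
#' Classical two-sided Student t-test with pooled variance per feature
#' column; keeps columns with `p < alpha` (strict), with no multiplicity
#' correction.
#'
#' @param X numeric subjects x features matrix.
#' @param y group labels (`"PD"` / `"HC"`), both classes with >= 2 members.
#' @param alpha selection threshold.
#' @return list with `keep` (selected column names) and `p` (all p-values).
#' @export
ttest_filter <- function(X, y, alpha = 0.05) {
  tt <- ttest_stats(X, y)
  p <- 2 * pt(-abs(tt$t), df = tt$df)
  list(keep = colnames(X)[!is.na(p) & p < alpha], p = p)
}

# Pooled-variance t statistics for every column, without p-values.
ttest_stats <- function(X, y) {
  g1 <- y == "PD"
  n1 <- sum(g1); n2 <- length(y) - n1
  if (n1 < 2L || n2 < 2L)
    af_stop("af_bad_groups", "each class needs >= 2 members")
  list(t = cpp_ttest_t(X, g1), df = n1 + n2 - 2)
}

# Fast filter used inside CV loops: |t| > critical value avoids computing
# 10^4 p-values per fold; identical selection to p < alpha (strict).
ttest_keep <- function(X, y, alpha) {
  tt <- ttest_stats(X, y)
  crit <- stats::qt(1 - alpha / 2, df = tt$df)
  colnames(X)[!is.na(tt$t) & abs(tt$t) > crit]
}

# ---- LASSO -----------------------------------------------------------------

#' LASSO logistic feature selection
#'
#' Minimizes the mean logistic loss plus `lam * sum(|beta|)` with an
#' unpenalized intercept (features are assumed pre-standardized) and
#' returns the features with nonzero coefficients. Fitting is by
#' coordinate descent (glmnet) along a short warm-start path ending at
#' `lam`.
#'
#' @param X standardized numeric matrix.
#' @param y binary labels (`"PD"` coded 1).
#' @param lam penalty weight.
#' @return list with `selected` (column names with `|beta| > 1e-8`),
#'   `beta` (their coefficients) and `intercept`.
#' @export
lasso_select <- function(X, y, lam) {
  yy <- as.integer(y == "PD")
  pad <- FALSE
  if (ncol(X) < 2L) {           # glmnet requires >= 2 columns
    X <- cbind(X, .pad. = 0)
    pad <- TRUE
  }
  path <- sort(unique(c(lam * c(8, 4, 2), lam)), decreasing = TRUE)
  fit <- tryCatch(
    suppressWarnings(    # small-fold class-size notices are expected
      glmnet::glmnet(X, yy, family = "binomial", lambda = path,
                     standardize = FALSE, intercept = TRUE, thresh = 1e-9)),
    error = function(e) af_stop("af_lasso_failure",
                                "LASSO failed at lambda=%g: %s",
                                lam, conditionMessage(e)))
  j <- which.min(abs(fit$lambda - lam))
  beta <- fit$beta[, j]
  if (pad) beta <- beta[names(beta) != ".pad."]
  nz <- abs(beta) > 1e-8
  list(selected = names(beta)[nz], beta = beta[nz],
       intercept = fit$a0[[j]])
}

# Nonzero-coefficient feature sets for every penalty on the grid from a
# single warm-started coordinate-descent path fit.
lasso_path_selections <- function(X, y, grid) {
  if (ncol(X) == 0L)
    return(rep(list(character(0)), length(grid)))
  yy <- as.integer(y == "PD")
  if (ncol(X) < 2L) X <- cbind(X, .pad. = 0)
  path <- sort(unique(c(max(grid) * c(8, 4, 2), grid)), decreasing = TRUE)
  fit <- tryCatch(
    suppressWarnings(
      glmnet::glmnet(X, yy, family = "binomial", lambda = path,
                     standardize = FALSE, intercept = TRUE, thresh = 1e-9)),
    error = function(e) af_stop("af_lasso_failure", "LASSO path failed: %s",
                                conditionMessage(e)))
  beta <- fit$beta
  feats <- rownames(beta)
  lapply(grid, function(lam) {
    j <- which.min(abs(fit$lambda - lam))
    nz <- feats[abs(beta[, j]) > 1e-8]
    setdiff(nz, ".pad.")
  })
}

# ---- SVM -------------------------------------------------------------------

#' Train a linear soft-margin SVM
#'
#' Linear-kernel C-SVM (libsvm via e1071) with PD as the positive class:
#' the returned decision score is `w . x + b`, positive for PD.
#'
#' @param X numeric matrix of selected features.
#' @param y labels with both classes present.
#' @param C cost parameter.
#' @return list of class `linear_svm` with `w`, `b`, `features`, `C`.
#' @export
train_svm <- function(X, y, C = 1.0) {
  if (ncol(X) < 1L) af_stop("af_empty_selection", "no features to train on")
  if (length(unique(y)) < 2L)
    af_stop("af_bad_groups", "both classes must be present")
  yf <- factor(y, levels = c("PD", "HC"))
  m <- e1071::svm(X, yf, kernel = "linear", cost = C, scale = FALSE,
                  tolerance = 1e-6, fitted = TRUE)
  w <- as.vector(t(m$coefs) %*% m$SV)
  b <- -m$rho
  # libsvm's sign convention depends on class ordering; orient so that
  # positive scores mean PD, using the stored fitted labels
  s <- as.vector(X %*% w + b)
  if (mean((s > 0) == (m$fitted == "PD")) < 0.5) {
    w <- -w; b <- -b
  }
  structure(list(w = stats::setNames(w, colnames(X)), b = b,
                 features = colnames(X), C = C),
            class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  newdata <- newdata[, object$features, drop = FALSE]
  score <- as.vector(newdata %*% object$w + object$b)
  list(score = score,
       label = ifelse(score > 0, "PD", "HC"))
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm> %d features, C = %g\n", length(x$w), x$C))
  invisible(x)
}

# ---- metrics ---------------------------------------------------------------

#' Confusion counts with PD as the positive class
#'
#' @param predicted,truth label vectors (`"PD"` / `"HC"`).
#' @return named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  c(TP = sum(predicted == "PD" & truth == "PD"),
    TN = sum(predicted == "HC" & truth == "HC"),
    FP = sum(predicted == "PD" & truth == "HC"),
    FN = sum(predicted == "HC" & truth == "PD"))
}

#' Classification metrics from confusion counts
#'
#' The seven standard formulas: accuracy, sensitivity (= recall),
#' specificity, precision, recall, F1 and balanced accuracy. A zero
#' denominator yields `NaN` with a warning.
#'
#' @param counts named vector with `TP`, `TN`, `FP`, `FN`.
#' @return named numeric vector of the seven metrics.
#' @export
confusion_metrics <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  if (any(c(tp, tn, fp, fn) < 0)) af_stop("af_bad_counts", "negative counts")
  div <- function(a, b, what) {
    if (b == 0) {
      warning(sprintf("%s undefined (zero denominator)", what), call. = FALSE)
      return(NaN)
    }
    a / b
  }
  acc <- div(tp + tn, tp + tn + fp + fn, "accuracy")
  sens <- div(tp, tp + fn, "sensitivity")
  spec <- div(tn, tn + fp, "specificity")
  prec <- div(tp, tp + fp, "precision")
  rec <- sens
  f1 <- if (is.nan(prec) || is.nan(rec) || (prec + rec) == 0) {
    warning("F1 undefined", call. = FALSE); NaN
  } else 2 * prec * rec / (prec + rec)
  c(accuracy = acc, sensitivity = sens, specificity = spec,
    precision = prec, recall = rec, f1 = f1,
    balanced_accuracy = 0.5 * (sens + spec))
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank formulation: the probability that a random PD score
#' exceeds a random HC score, with ties contributing 1/2.
#'
#' @param scores numeric decision scores (larger = more PD-like).
#' @param labels class labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "PD"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    af_stop("af_bad_groups", "both classes needed for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---- cross-validation machinery -------------------------------------------

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin into k folds.
stratified_folds <- function(y, k, seed) {
  if (min(table(y)) < k)
    af_stop("af_bad_groups",
            "need >= %d subjects per class for %d stratified folds", k, k)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

majority_class <- function(y) {
  tab <- table(factor(y, levels = c("PD", "HC")))
  if (tab[["PD"]] >= tab[["HC"]]) "PD" else "HC"  # tie -> PD (positive class)
}

# Selection + model fit on one training set at a fixed lambda.
fit_fold_model <- function(X, y, lam, alpha, svm_C) {
  keep <- ttest_keep(X, y, alpha)
  if (!length(keep))
    return(list(selected = character(0), model = NULL,
                fallback = majority_class(y)))
  las <- lasso_select(X[, keep, drop = FALSE], y, lam)
  if (!length(las$selected))
    return(list(selected = character(0), model = NULL,
                fallback = majority_class(y)))
  model <- train_svm(X[, las$selected, drop = FALSE], y, C = svm_C)
  list(selected = las$selected, model = model, fallback = NULL)
}

predict_fold_model <- function(fm, X) {
  if (is.null(fm$model)) {
    list(score = rep(if (fm$fallback == "PD") 1e-6 else -1e-6, nrow(X)),
         label = rep(fm$fallback, nrow(X)))
  } else {
    predict(fm$model, X)
  }
}

#' Inner cross-validated selection of the LASSO penalty
#'
#' For every penalty on the grid, runs `k_inner`-fold cross-validation on
#' the training set, where each inner fold reruns the t-test filter and
#' the LASSO on its own training part (no statistics touch the held-out
#' part), trains the linear SVM on the selected features and scores the
#' held-out part. Returns the accuracy-maximizing penalty; ties go to the
#' larger penalty (stronger shrinkage). Inner folds where nothing is
#' selected fall back to the training majority class.
#'
#' @param X_train,y_train the (outer) training set.
#' @param grid increasing penalty grid.
#' @param k_inner inner fold count.
#' @param seed fold-assignment seed.
#' @param alpha t-filter threshold.
#' @param svm_C SVM cost.
#' @return the selected penalty (scalar).
#' @export
inner_select_lambda <- function(X_train, y_train, grid, k_inner, seed,
                                alpha = 0.05, svm_C = 1.0) {
  if (!length(grid)) af_stop("af_bad_config", "empty lambda grid")
  folds <- stratified_folds(y_train, k_inner, seed)
  correct <- stats::setNames(numeric(length(grid)), format(grid))
  any_selected <- FALSE
  for (f in seq_len(k_inner)) {
    tr <- folds != f; te <- folds == f
    Xtr <- X_train[tr, , drop = FALSE]; ytr <- y_train[tr]
    Xte <- X_train[te, , drop = FALSE]; yte <- y_train[te]
    keep <- ttest_keep(Xtr, ytr, alpha)
    sel_by_lam <- lasso_path_selections(Xtr[, keep, drop = FALSE], ytr, grid)
    cache <- new.env(parent = emptyenv())
    for (gi in seq_along(grid)) {
      sel <- sel_by_lam[[gi]]
      if (length(sel)) {
        any_selected <- TRUE
        key <- paste(sel, collapse = "\r")
        fm <- get0(key, cache)
        if (is.null(fm)) {
          fm <- train_svm(Xtr[, sel, drop = FALSE], ytr, C = svm_C)
          assign(key, fm, cache)
        }
        pred <- predict(fm, Xte)$label
      } else {
        pred <- rep(majority_class(ytr), sum(te))
      }
      correct[gi] <- correct[gi] + sum(pred == yte)
    }
  }
  if (!any_selected)
    af_stop("af_empty_selection",
            "every lambda yielded an empty selection in every inner fold")
  best <- max(correct)
  grid[max(which(correct == best))]   # tie -> larger lambda
}

# ---- nested cross-validation ----------------------------------------------

#' Nested cross-validated LASSO + SVM classification
#'
#' The performance-estimation engine: per repeat `r` (fold seed
#' `base_seed + r`), subjects are split into `k_outer` stratified outer
#' folds. For each outer fold, [inner_select_lambda()] picks the penalty
#' on the outer-training set only; the t-test filter, LASSO selection and
#' SVM are then refit on the full outer-training set at that penalty and
#' evaluated on the outer test fold. Test subjects never touch selection
#' or training. The summary averages the seven metrics over all
#' `k_outer * n_repeats` folds (folds with undefined metrics are excluded
#' from that metric's mean); AUC is computed from the pooled outer-fold
#' decision scores of each repeat and averaged over repeats.
#'
#' The feature table must already be standardized (see
#' [zscore_fit_apply()]); standardization is a per-set step, not a
#' per-fold step.
#'
#' @param table standardized subjects x features matrix.
#' @param y group labels aligned with the rows.
#' @param config a [run_config()].
#' @return object of class `nested_cv`: `fold_records`, `summary`
#'   (mean metrics + AUC), `per_repeat`, `lambda_table`, `config`.
#' @export
nested_cv <- function(table, y, config = run_config()) {
  X <- unclass(table)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  validate_run_config(config)
  records <- list()
  per_repeat <- NULL
  for (r in seq_len(config$n_repeats)) {
    rep_seed <- config$base_seed + r
    folds <- stratified_folds(y, config$k_outer, rep_seed)
    pooled_scores <- numeric(0); pooled_truth <- character(0)
    fold_metrics <- NULL
    for (f in seq_len(config$k_outer)) {
      tr <- folds != f; te <- folds == f
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      Xte <- X[te, , drop = FALSE]; yte <- y[te]
      # if no lambda ever selects anything on this training set (possible
      # on null or label-permuted data), fall back to the largest penalty:
      # the outer fold then uses the majority-class fallback, keeping
      # permutation reruns well-defined
      lam <- tryCatch(
        inner_select_lambda(Xtr, ytr, config$lambda_grid, config$k_inner,
                            seed = derive_seed(rep_seed, f),
                            alpha = config$alpha, svm_C = config$svm_C),
        af_empty_selection = function(e) {
          af_log("nested_cv", "repeat %d fold %d: empty inner selections; majority fallback", r, f)
          max(config$lambda_grid)
        })
      fm <- fit_fold_model(Xtr, ytr, lam, config$alpha, config$svm_C)
      pred <- predict_fold_model(fm, Xte)
      met <- suppressWarnings(confusion_metrics(
        confusion_counts(pred$label, yte)))
      records[[length(records) + 1L]] <- list(
        repeat_index = r, fold = f, lambda = lam,
        selected = fm$selected,
        weights = if (is.null(fm$model)) numeric(0) else fm$model$w,
        test_subjects = rownames(X)[te],
        predicted = pred$label, scores = pred$score, truth = yte)
      fold_metrics <- rbind(fold_metrics, met)
      pooled_scores <- c(pooled_scores, pred$score)
      pooled_truth <- c(pooled_truth, yte)
    }
    per_repeat <- rbind(per_repeat,
                        c(colMeans(fold_metrics, na.rm = TRUE),
                          auc = roc_auc(pooled_scores, pooled_truth)))
  }
  fold_mat <- do.call(rbind, lapply(records, function(rec)
    suppressWarnings(confusion_metrics(
      confusion_counts(rec$predicted, rec$truth)))))
  summary <- c(colMeans(fold_mat, na.rm = TRUE),
               auc = mean(per_repeat[, "auc"]))
  af_log("nested_cv",
         "base_seed=%d %dx%d CV x%d repeats: mean accuracy %.3f, AUC %.3f",
         config$base_seed, config$k_outer, config$k_inner, config$n_repeats,
         summary[["accuracy"]], summary[["auc"]])
  structure(list(fold_records = records, summary = summary,
                 per_repeat = per_repeat,
                 lambda_table = table(vapply(records, `[[`, 0.0, "lambda")),
                 n_subjects = nrow(X), config = config),
            class = "nested_cv")
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf("<nested_cv> %d-fold x %d repeats on %d subjects\n",
              x$config$k_outer, x$config$n_repeats, x$n_subjects))
  cat(sprintf("  mean accuracy %.4f  AUC %.4f  sensitivity %.4f  specificity %.4f\n",
              x$summary[["accuracy"]], x$summary[["auc"]],
              x$summary[["sensitivity"]], x$summary[["specificity"]]))
  cat(sprintf("  modal lambda %.2f\n", select_modal_lambda(x$fold_records)))
  invisible(x)
}

#' @export
summary.nested_cv <- function(object, ...) {
  out <- list(metrics = object$summary,
              per_repeat = object$per_repeat,
              lambda_table = object$lambda_table,
              modal_lambda = select_modal_lambda(object$fold_records))
  class(out) <- "summary.nested_cv"
  out
}

#' @export
print.summary.nested_cv <- function(x, ...) {
  cat("Mean metrics over all outer folds and repeats:\n")
  print(round(x$metrics, 4))
  cat("\nPenalty selection frequencies:\n")
  print(x$lambda_table)
  cat(sprintf("\nModal lambda: %.2f\n", x$modal_lambda))
  invisible(x)
}

#' Modal penalty across all outer folds
#'
#' The penalty chosen most frequently across all outer folds and repeats;
#' ties go to the larger penalty.
#'
#' @param fold_records `fold_records` from a [nested_cv()] fit.
#' @return the modal penalty (scalar).
#' @export
select_modal_lambda <- function(fold_records) {
  if (!length(fold_records)) af_stop("af_bad_input", "no fold records")
  lams <- vapply(fold_records, `[[`, 0.0, "lambda")
  tab <- table(lams)
  winners <- as.numeric(names(tab)[tab == max(tab)])
  max(winners)
}

# ---- final model and external validation -----------------------------------

#' Fit the final model on the whole primary set
#'
#' Runs the t-test filter and LASSO selection on all primary subjects at
#' the supplied (modal) penalty, then trains the linear SVM on the
#' surviving features. The selected feature list is frozen into the model
#' for external validation.
#'
#' @param table standardized primary feature matrix.
#' @param y group labels.
#' @param lambda penalty, normally from [select_modal_lambda()].
#' @param config a [run_config()].
#' @return object of class `final_model` with the frozen feature set,
#'   SVM weights and the penalty used.
#' @export
fit_final_model <- function(table, y, lambda, config = run_config()) {
  X <- unclass(table)
  fm <- fit_fold_model(X, as.character(y), lambda, config$alpha, config$svm_C)
  if (is.null(fm$model))
    af_stop("af_empty_selection",
            "final selection is empty at lambda=%g; the empty-selection fallback applies only inside CV folds",
            lambda)
  af_log("final_model", "lambda=%g froze %d features", lambda,
         length(fm$selected))
  structure(list(lambda = lambda, features = fm$selected,
                 svm = fm$model, config = config),
            class = "final_model")
}

#' @export
print.final_model <- function(x, ...) {
  cat(sprintf("<final_model> lambda = %g, %d frozen features\n",
              x$lambda, length(x$features)))
  invisible(x)
}

#' @export
coef.final_model <- function(object, ...) object$svm$w

#' @export
predict.final_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing))
    af_stop("af_missing_feature",
            "frozen feature %s missing from validation table", missing[1])
  predict(object$svm, unclass(newdata))
}

#' Externally validate a frozen final model
#'
#' Applies the frozen model (no refitting, no reselection) to an external
#' set that has been standardized with its own statistics, and reports the
#' seven metrics plus AUC.
#'
#' @param final_model a [fit_final_model()] result.
#' @param validation_table standardized external feature matrix.
#' @param y_val external labels.
#' @return named numeric vector of metrics.
#' @export
external_validate <- function(final_model, validation_table, y_val) {
  pred <- predict(final_model, validation_table)
  met <- suppressWarnings(confusion_metrics(
    confusion_counts(pred$label, as.character(y_val))))
  c(met, auc = roc_auc(pred$score, as.character(y_val)))
}

#' Fit the final model with penalty fallback
#'
#' Convenience wrapper around [select_modal_lambda()] and
#' [fit_final_model()]: if the modal penalty selects nothing on the full
#' set (fold-level penalties are evaluated on subsets whose column SDs
#' exceed 1, so a penalty can be selectable in folds yet empty on the
#' full set), falls back through the remaining penalties in fold-frequency
#' order, then down the grid, logging any substitution.
#'
#' @param table standardized primary feature matrix.
#' @param y group labels.
#' @param fold_records `fold_records` from [nested_cv()].
#' @param config a [run_config()].
#' @return a `final_model` (see [fit_final_model()]); errors only if every
#'   penalty yields an empty selection.
#' @export
finalize_model <- function(table, y, fold_records, config = run_config()) {
  modal <- select_modal_lambda(fold_records)
  lams <- vapply(fold_records, `[[`, 0.0, "lambda")
  tab <- sort(table(lams), decreasing = TRUE)
  for (lam in unique(c(modal, as.numeric(names(tab)),
                       rev(config$lambda_grid)))) {
    final <- tryCatch(fit_final_model(table, y, lam, config),
                      af_empty_selection = function(e) NULL)
    if (!is.null(final)) {
      if (lam != modal)
        af_log("final_model",
               "modal lambda %g empty on the full set; using %g", modal, lam)
      return(final)
    }
  }
  af_stop("af_empty_selection", "no penalty yields a nonempty final model")
}

# ---- permutation test ------------------------------------------------------

#' Permutation test of classifier significance
#'
#' Shuffles the class labels `n_perm` times (each shuffle a full
#' permutation, i.e. sampling without replacement) and reruns the entire
#' nested cross-validated pipeline — selection inside the folds included —
#' on each shuffled labeling. The p-value is `(1 + N_GP) / (1 + N)` where
#' `N_GP` counts permutations whose statistic strictly exceeds the
#' observed one; the smallest attainable p is `1 / (1 + N)`. Reduced
#' permutation counts for desk-scale runs are supported and logged.
#'
#' @param table standardized feature matrix.
#' @param y observed labels.
#' @param config a [run_config()] used for every nested-CV run.
#' @param n_perm number of permutations (default from `config`).
#' @param stat_kind `"accuracy"` or `"auc"`.
#' @param observed_stat observed statistic; computed by running
#'   [nested_cv()] on the true labels when omitted.
#' @param seed permutation RNG seed (default derived from the config).
#' @return object of class `permutation_result` with `N`, `N_GP`, `p`,
#'   `observed`, `perm_stats`.
#' @export
permutation_test <- function(table, y, config = run_config(),
                             n_perm = config$n_permutations,
                             stat_kind = c("accuracy", "auc"),
                             observed_stat = NULL, seed = NULL) {
  stat_kind <- match.arg(stat_kind)
  if (n_perm < 1L) af_stop("af_bad_config", "n_perm must be >= 1")
  if (n_perm != 1000L)
    af_log("permutation", "reduced permutation count n_perm=%d", n_perm)
  y <- as.character(y)
  if (is.null(observed_stat))
    observed_stat <- nested_cv(table, y, config)$summary[[stat_kind]]
  if (is.null(seed)) seed <- derive_seed(config$base_seed, 777L)
  perms <- with_seed(seed, replicate(n_perm, sample(y), simplify = FALSE))
  perm_stats <- vapply(perms, function(yp)
    nested_cv(table, yp, config)$summary[[stat_kind]], 0.0)
  n_gp <- sum(perm_stats > observed_stat)
  p <- (1 + n_gp) / (1 + n_perm)
  af_log("permutation", "N=%d N_GP=%d p=%.5f (%s)", n_perm, n_gp, p, stat_kind)
  structure(list(N = n_perm, N_GP = n_gp, p = p, stat_kind = stat_kind,
                 observed = observed_stat, perm_stats = perm_stats),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s: observed %.4f, N = %d, N_GP = %d, p = %.5f\n",
              x$stat_kind, x$observed, x$N, x$N_GP, x$p))
  invisible(x)
}
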