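make_xy <- function(n_per = 12, p = 40, informative = 0, shift = 2,
                    seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p,
              dimnames = list(sprintf("s%02d", 1:(2 * n_per)),
                              sprintf("R%03d|Mean|original", 1:p)))
  y <- rep(c("PD", "HC"), each = n_per)
  if (informative > 0)
    X[y == "PD", seq_len(informative)] <-
      X[y == "PD", seq_len(informative)] + shift
  list(X = X, y = y)
}

test_that("z-scoring gives population-SD columns with mean 0, per set", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 0, 2), cst = c(5, 5, 5))
  rownames(m) <- c("s1", "s2", "s3")
  z <- zscore_fit_apply(m)
  expect_equal(unname(z$table[, "a"]),
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-10)
  expect_identical(z$dropped, "cst")
  expect_true(all(abs(colMeans(z$table)) < 1e-10))
  expect_true(all(abs(sqrt(colMeans(z$table^2)) - 1) < 1e-10))
  # an external set standardized with its own statistics is also centered
  m2 <- m[, 1:2] * 10 + 3
  z2 <- zscore_fit_apply(m2)
  expect_true(all(abs(colMeans(z2$table)) < 1e-10))
  expect_error(zscore_fit_apply(m[1, , drop = FALSE]), class = "af_bad_table")
})

test_that("t filter is calibrated on null columns and catches strong effects", {
  counts <- vapply(1:40, function(i) {
    d <- make_xy(n_per = 20, p = 100, seed = 100 + i)
    length(ttest_filter(d$X, d$y, 0.05)$keep)
  }, 0.0)
  expect_gt(mean(counts), 3.5)   # nominal 5 of 100
  expect_lt(mean(counts), 6.5)
  d <- make_xy(n_per = 20, p = 5, informative = 1, shift = 3, seed = 9)
  flt <- ttest_filter(d$X, d$y, 0.05)
  expect_true(colnames(d$X)[1] %in% flt$keep)
  expect_lt(flt$p[1], 1e-10)
  # strict threshold and agreement with stats::t.test
  pref <- t.test(d$X[d$y == "PD", 2], d$X[d$y == "HC", 2],
                 var.equal = TRUE)$p.value
  expect_equal(unname(flt$p[2]), pref, tolerance = 1e-12)
  expect_error(ttest_filter(d$X[c(1, 21), ], d$y[c(1, 21)]),
               class = "af_bad_groups")
})

test_that("LASSO obeys the KKT zero-selection threshold", {
  d <- make_xy(n_per = 10, p = 6, seed = 3)
  X <- scale(d$X)[, ]
  y01 <- as.integer(d$y == "PD")
  lam_max <- max(abs(crossprod(X, y01 - mean(y01)))) / nrow(X)
  sel <- lasso_select(X, d$y, lam = lam_max * 1.01)
  expect_length(sel$selected, 0L)
  sel2 <- lasso_select(X, d$y, lam = lam_max * 0.5)
  expect_gt(length(sel2$selected), 0L)
})

test_that("LASSO matches an independent proximal-gradient oracle", {
  set.seed(21)
  n <- 40
  x1 <- rnorm(n); y <- ifelse(x1 + 0.3 * rnorm(n) > 0, "PD", "HC")
  X <- cbind(sig = x1, noise = rnorm(n))
  X <- scale(X)[, ]
  rownames(X) <- sprintf("s%02d", 1:n)
  # the perfectly predictive feature enters first along the path
  sel_path <- lapply(c(0.3, 0.15, 0.05),
                     function(l) lasso_select(X, y, l)$selected)
  entered <- unlist(lapply(sel_path, function(s) s))[1]
  expect_identical(entered, "sig")
  fit <- lasso_select(X, y, 0.1)
  orc <- lasso_ista_oracle(X, as.integer(y == "PD"), 0.1,
                           iters = 300000, step = 0.5)
  expect_equal(unname(fit$beta[fit$selected]),
               orc$beta[abs(orc$beta) > 1e-8], tolerance = 1e-4)
  expect_equal(fit$intercept, orc$intercept, tolerance = 1e-3)
})

test_that("linear SVM reproduces the two-point maximum-margin solution", {
  x1 <- c(1, 1); x2 <- c(-1, -1)
  X <- rbind(x1, x2, x1 + c(2, 0), x2 - c(2, 0))
  colnames(X) <- c("f1", "f2")
  y <- c("PD", "HC", "PD", "HC")
  m <- train_svm(X, y, C = 1)
  orc <- svm_two_point_oracle(x1, x2)
  expect_equal(unname(m$w), orc$w, tolerance = 1e-6)
  expect_equal(m$b, orc$b, tolerance = 1e-6)
  pred <- predict(m, X)
  expect_identical(pred$label, y)                 # separable: zero error
  # scores are the signed distance scaled by ||w||: monotone in distance
  expect_true(all(diff(order(pred$score)) != 0))
  expect_equal(pred$score, as.vector(X %*% m$w + m$b))
})

test_that("linear SVM weights match a quadratic-programming oracle on 6 points", {
  skip_if_not_installed("kernlab")
  set.seed(4)
  X <- rbind(matrix(rnorm(6, 1.5), 3, 2), matrix(rnorm(6, -1.5), 3, 2))
  colnames(X) <- c("f1", "f2")
  yv <- c(1, 1, 1, -1, -1, -1)
  y <- ifelse(yv > 0, "PD", "HC")
  m <- train_svm(X, y, C = 1)
  Q <- (yv %o% yv) * (X %*% t(X))
  qp <- kernlab::ipop(c = rep(-1, 6), H = Q, A = t(yv), b = 0,
                      l = rep(0, 6), u = rep(1, 6), r = 0, sigf = 9)
  alpha <- kernlab::primal(qp)
  w_or <- as.vector(t(X) %*% (alpha * yv))
  sv <- which(alpha > 1e-6 & alpha < 1 - 1e-6)
  b_or <- mean(yv[sv] - X[sv, , drop = FALSE] %*% w_or)
  expect_equal(unname(m$w), w_or, tolerance = 1e-5)
  expect_equal(m$b, b_or, tolerance = 1e-5)
})

test_that("confusion metrics follow the seven printed formulas", {
  met <- confusion_metrics(c(TP = 9, TN = 7, FP = 3, FN = 1))
  expect_equal(met[["accuracy"]], 0.8)
  expect_equal(met[["sensitivity"]], 0.9)
  expect_equal(met[["specificity"]], 0.7)
  expect_equal(met[["precision"]], 0.75)
  expect_equal(met[["recall"]], 0.9)
  expect_equal(met[["f1"]], 2 * 0.75 * 0.9 / (0.75 + 0.9))
  expect_equal(met[["balanced_accuracy"]], 0.8)
  w <- capture_warnings(
    m0 <- confusion_metrics(c(TP = 0, TN = 5, FP = 0, FN = 5)))
  expect_match(w, "precision|F1", all = TRUE)
  expect_true(is.nan(m0[["precision"]]))
})

test_that("metric identities hold on random confusion counts", {
  set.seed(12)
  for (i in 1:25) {
    cts <- c(TP = rbinom(1, 30, 0.5) + 1, TN = rbinom(1, 30, 0.5) + 1,
             FP = rbinom(1, 30, 0.3) + 1, FN = rbinom(1, 30, 0.3) + 1)
    met <- confusion_metrics(cts)
    # independent direct evaluation
    expect_equal(met[["accuracy"]],
                 (cts[["TP"]] + cts[["TN"]]) / sum(cts), tolerance = 1e-12)
    expect_equal(met[["balanced_accuracy"]],
                 0.5 * (met[["sensitivity"]] + met[["specificity"]]),
                 tolerance = 1e-12)
    expect_equal(met[["f1"]],
                 2 * met[["precision"]] * met[["recall"]] /
                   (met[["precision"]] + met[["recall"]]), tolerance = 1e-12)
  }
})

test_that("rank AUC equals trapezoidal ROC integration and handles ties", {
  set.seed(13)
  for (i in 1:10) {
    n <- 40
    labels <- sample(rep(c("PD", "HC"), each = n / 2))
    scores <- round(rnorm(n), 1)      # induces ties
    expect_equal(roc_auc(scores, labels),
                 auc_trapezoid_oracle(scores, labels), tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(3, 4, 1, 2), c("PD", "PD", "HC", "HC")), 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c("PD", "PD", "HC", "HC")), 0)
  aucs <- vapply(1:50, function(i) {
    roc_auc(rnorm(100), sample(rep(c("PD", "HC"), 50)))
  }, 0.0)
  se <- sqrt(101 / (12 * 50 * 50))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se / sqrt(50))
  expect_error(roc_auc(1:3, c("PD", "PD", "PD")), class = "af_bad_groups")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- rnorm(60)
  labels <- ifelse(scores + rnorm(60) > 0, "PD", "HC")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("HC", "PD"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("inner lambda selection follows the grid, accuracy and tie rules", {
  d <- make_xy(n_per = 12, p = 30, informative = 3, shift = 2, seed = 31)
  X <- scale(d$X)[, ]
  expect_equal(inner_select_lambda(X, d$y, grid = 0.2, k_inner = 3,
                                   seed = 5), 0.2)
  lam <- inner_select_lambda(X, d$y, grid = seq(0.05, 0.6, 0.05),
                             k_inner = 3, seed = 5)
  expect_true(lam %in% seq(0.05, 0.6, 0.05))
  # with many noise dimensions the penalty floor is rarely optimal
  picks <- vapply(1:10, function(i) {
    d <- make_xy(n_per = 12, p = 150, informative = 2, shift = 1.6,
                 seed = 300 + i)
    inner_select_lambda(scale(d$X)[, ], d$y, grid = seq(0.05, 0.6, 0.05),
                        k_inner = 3, seed = i)
  }, 0.0)
  expect_gte(mean(picks > 0.05), 0.8)
})

test_that("modal lambda uses frequency with ties to the larger penalty", {
  recs <- function(lams) lapply(lams, function(l) list(lambda = l))
  expect_equal(select_modal_lambda(recs(rep(0.3, 5))), 0.3)
  expect_equal(select_modal_lambda(recs(c(rep(0.2, 3), rep(0.45, 3)))), 0.45)
  expect_equal(select_modal_lambda(recs(c(0.2, 0.2, 0.3))), 0.2)
})

test_that("nested CV keeps test subjects out of selection (leakage freedom)", {
  d <- make_xy(n_per = 12, p = 50, informative = 4, shift = 2, seed = 41)
  X <- scale(d$X)[, ]
  cfg <- run_config(k_outer = 3, k_inner = 3, n_repeats = 1, base_seed = 77)
  fit1 <- nested_cv(X, d$y, cfg)
  rec1 <- fit1$fold_records[[1]]
  X2 <- X
  set.seed(99)
  X2[rec1$test_subjects, ] <- rnorm(length(rec1$test_subjects) * ncol(X))
  fit2 <- nested_cv(X2, d$y, cfg)
  rec2 <- fit2$fold_records[[1]]
  expect_identical(rec1$selected, rec2$selected)
  expect_identical(rec1$lambda, rec2$lambda)
  expect_equal(rec1$weights, rec2$weights)
})

test_that("nested CV partitions subjects and is deterministic given the seed", {
  d <- make_xy(n_per = 10, p = 30, informative = 2, shift = 2, seed = 51)
  X <- scale(d$X)[, ]
  cfg <- run_config(k_outer = 4, k_inner = 3, n_repeats = 2, base_seed = 5)
  fit <- nested_cv(X, d$y, cfg)
  for (r in 1:2) {
    test_ids <- unlist(lapply(fit$fold_records[
      vapply(fit$fold_records, `[[`, 0, "repeat_index") == r],
      `[[`, "test_subjects"))
    expect_identical(sort(test_ids), sort(rownames(X)))
  }
  fit2 <- nested_cv(X, d$y, cfg)
  expect_equal(fit$summary, fit2$summary)
  expect_identical(lapply(fit$fold_records, `[[`, "selected"),
                   lapply(fit2$fold_records, `[[`, "selected"))
  expect_s3_class(fit, "nested_cv")
  expect_output(print(fit), "mean accuracy")
  expect_output(print(summary(fit)), "Modal lambda")
})

test_that("the final model freezes features and refuses refitting on new data", {
  d <- make_xy(n_per = 15, p = 40, informative = 3, shift = 2.5, seed = 61)
  X <- scale(d$X)[, ]
  cfg <- run_config(k_outer = 3, k_inner = 3, n_repeats = 1, base_seed = 6)
  final <- fit_final_model(X, d$y, lambda = 0.2, config = cfg)
  final2 <- fit_final_model(X, d$y, lambda = 0.2, config = cfg)
  expect_identical(final$features, final2$features)
  expect_equal(coef(final), coef(final2))
  expect_gt(length(final$features), 0L)
  # external validation with the frozen set
  d_val <- make_xy(n_per = 15, p = 40, informative = 3, shift = 2.5,
                   seed = 62)
  Xv <- scale(d_val$X)[, ]
  met <- external_validate(final, Xv, d_val$y)
  expect_true(all(c("accuracy", "auc") %in% names(met)))
  expect_gt(met[["accuracy"]], 0.7)
  # a missing frozen feature is an error
  Xv2 <- Xv[, setdiff(colnames(Xv), final$features[1])]
  expect_error(external_validate(final, Xv2, d_val$y),
               class = "af_missing_feature")
  # label-shuffled validation collapses toward chance
  set.seed(7)
  accs <- vapply(1:20, function(i)
    external_validate(final, Xv, sample(d_val$y))[["accuracy"]], 0.0)
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("empty final selection at huge penalty raises the documented error", {
  d <- make_xy(n_per = 10, p = 20, seed = 71)
  X <- scale(d$X)[, ]
  expect_error(fit_final_model(X, d$y, lambda = 50,
                               config = run_config(k_outer = 2, k_inner = 2,
                                                   n_repeats = 1)),
               class = "af_empty_selection")
})

test_that("permutation p follows (1 + N_GP)/(1 + N) and is monotone in the statistic", {
  d <- make_xy(n_per = 8, p = 20, informative = 2, shift = 2, seed = 81)
  X <- scale(d$X)[, ]
  cfg <- run_config(k_outer = 2, k_inner = 2, n_repeats = 1, base_seed = 3)
  pr <- permutation_test(X, d$y, cfg, n_perm = 12, stat_kind = "accuracy",
                         observed_stat = 0.9, seed = 55)
  expect_identical(pr$N, 12)
  expect_equal(pr$p, (1 + pr$N_GP) / 13)
  expect_gte(pr$p, 1 / 13)
  expect_lte(pr$p, 1)
  expect_equal(pr$N_GP, sum(pr$perm_stats > 0.9))
  # same permutations, lower observed statistic -> p can only grow
  pr_lo <- permutation_test(X, d$y, cfg, n_perm = 12,
                            stat_kind = "accuracy",
                            observed_stat = 0.4, seed = 55)
  expect_identical(pr_lo$perm_stats, pr$perm_stats)
  expect_gte(pr_lo$p, pr$p)
  expect_error(permutation_test(X, d$y, cfg, n_perm = 0),
               class = "af_bad_config")
})
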