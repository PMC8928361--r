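# Independent brute-force oracles. These are deliberately written as
# direct transcriptions of the defining formulas (plain loops, no shared
# code with the package internals) and are only ever run on tiny inputs.

# The 13 direction offsets (one per antipodal pair).
ORACLE_DIRS <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# --- first-order -----------------------------------------------------------
fo_oracle <- function(v, n_bins = 32L) {
  n <- length(v)
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  m4 <- sum((v - mu)^4) / n
  lo <- min(v); hi <- max(v)
  if (hi > lo) {
    lev <- pmin(floor((v - lo) / (hi - lo) * n_bins) + 1, n_bins)
  } else lev <- rep(1, n)
  p <- as.vector(table(factor(lev, levels = 1:n_bins))) / n
  pp <- p[p > 0]
  srt <- sort(v)
  q90 <- {
    h <- (n - 1) * 0.9
    lo_i <- floor(h) + 1
    if (lo_i < n) srt[lo_i] + (h - floor(h)) * (srt[lo_i + 1] - srt[lo_i])
    else srt[n]
  }
  c(Minimum = min(v), Maximum = max(v), Mean = mu,
    Median = if (n %% 2) srt[(n + 1) / 2] else (srt[n / 2] + srt[n / 2 + 1]) / 2,
    Range = max(v) - min(v), Variance = m2, StandardDeviation = sqrt(m2),
    Skewness = if (m2 > 0) m3 / m2^(3 / 2) else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Energy = sum(v^2), RootMeanSquare = sqrt(sum(v^2) / n),
    MeanAbsoluteDeviation = sum(abs(v - mu)) / n,
    Uniformity = sum(pp^2), Entropy = -sum(pp * log2(pp)),
    Percentile90 = q90)
}

# --- co-occurrence ---------------------------------------------------------
# Exhaustive pair enumeration over the 13 directions, symmetric counts.
glcm_matrix_oracle <- function(lev, n_bins) {
  d <- dim(lev)
  M <- matrix(0, n_bins, n_bins)
  for (k in seq_len(nrow(ORACLE_DIRS))) {
    off <- ORACLE_DIRS[k, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      if (lev[x, y, z] == 0) next
      x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3])
        next
      if (lev[x2, y2, z2] == 0) next
      a <- lev[x, y, z]; b <- lev[x2, y2, z2]
      M[a, b] <- M[a, b] + 1
      M[b, a] <- M[b, a] + 1
    }
  }
  M
}

glcm_features_oracle <- function(M) {
  n_bins <- nrow(M)
  P <- M / sum(M)
  px <- sapply(1:n_bins, function(i) sum(P[i, ]))
  mu <- sum((1:n_bins) * px)
  sig2 <- sum(((1:n_bins) - mu)^2 * px)
  f <- numeric(0)
  s <- function(fun) {
    acc <- 0
    for (i in 1:n_bins) for (j in 1:n_bins)
      acc <- acc + fun(i, j) * P[i, j]
    acc
  }
  HXY <- 0
  for (i in 1:n_bins) for (j in 1:n_bins)
    if (P[i, j] > 0) HXY <- HXY - P[i, j] * log2(P[i, j])
  HX <- 0
  for (i in 1:n_bins) if (px[i] > 0) HX <- HX - px[i] * log2(px[i])
  HXY1 <- 0; HXY2 <- 0
  for (i in 1:n_bins) for (j in 1:n_bins) {
    q <- px[i] * px[j]
    if (q > 0) {
      HXY1 <- HXY1 - P[i, j] * log2(q)
      HXY2 <- HXY2 - q * log2(q)
    }
  }
  pxmy <- sapply(0:(n_bins - 1), function(kk) {
    acc <- 0
    for (i in 1:n_bins) for (j in 1:n_bins)
      if (abs(i - j) == kk) acc <- acc + P[i, j]
    acc
  })
  pxpy <- sapply(2:(2 * n_bins), function(kk) {
    acc <- 0
    for (i in 1:n_bins) for (j in 1:n_bins)
      if (i + j == kk) acc <- acc + P[i, j]
    acc
  })
  sa <- sum((2:(2 * n_bins)) * pxpy)
  c(Autocorrelation = s(function(i, j) i * j),
    ClusterProminence = s(function(i, j) (i + j - 2 * mu)^4),
    ClusterShade = s(function(i, j) (i + j - 2 * mu)^3),
    ClusterTendency = s(function(i, j) (i + j - 2 * mu)^2),
    Contrast = s(function(i, j) (i - j)^2),
    Correlation = if (sig2 > 0) (s(function(i, j) i * j) - mu^2) / sig2 else 0,
    DifferenceEntropy = -sum(sapply(pxmy, function(p) if (p > 0) p * log2(p) else 0)),
    Dissimilarity = s(function(i, j) abs(i - j)),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    Homogeneity1 = s(function(i, j) 1 / (1 + abs(i - j))),
    Homogeneity2 = s(function(i, j) 1 / (1 + (i - j)^2)),
    IMC1 = if (HX > 0) (HXY - HXY1) / HX else 0,
    IMC2 = if (HX > 0) sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY)))) else 0,
    IDMN = s(function(i, j) 1 / (1 + (i - j)^2 / n_bins^2)),
    IDN = s(function(i, j) 1 / (1 + abs(i - j) / n_bins)),
    InverseVariance = s(function(i, j) if (i != j) 1 / (i - j)^2 else 0),
    MaximumProbability = max(P),
    SumAverage = sa,
    SumEntropy = -sum(sapply(pxpy, function(p) if (p > 0) p * log2(p) else 0)),
    SumVariance = sum(((2:(2 * n_bins)) - sa)^2 * pxpy),
    JointVariance = s(function(i, j) (i - mu)^2))
}

# --- run length ------------------------------------------------------------
# Explicit run enumeration: walk every line through every start voxel.
glrlm_oracle <- function(lev, n_bins, n_voxels = sum(lev > 0)) {
  d <- dim(lev)
  inb <- function(x, y, z) x >= 1 && x <= d[1] && y >= 1 && y <= d[2] &&
    z >= 1 && z <= d[3]
  feats <- matrix(NA_real_, nrow(ORACLE_DIRS), 11)
  for (k in seq_len(nrow(ORACLE_DIRS))) {
    off <- ORACLE_DIRS[k, ]
    runs <- NULL  # rows: (level, length)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      l <- lev[x, y, z]
      if (l == 0) next
      px <- x - off[1]; py <- y - off[2]; pz <- z - off[3]
      if (inb(px, py, pz) && lev[px, py, pz] == l) next  # not a run start
      len <- 1
      cx <- x + off[1]; cy <- y + off[2]; cz <- z + off[3]
      while (inb(cx, cy, cz) && lev[cx, cy, cz] == l) {
        len <- len + 1
        cx <- cx + off[1]; cy <- cy + off[2]; cz <- cz + off[3]
      }
      runs <- rbind(runs, c(l, len))
    }
    Nr <- nrow(runs)
    lv <- runs[, 1]; rl <- runs[, 2]
    gln <- sum(sapply(unique(lv), function(g) sum(lv == g)^2))
    rln <- sum(sapply(unique(rl), function(g) sum(rl == g)^2))
    feats[k, ] <- c(
      SRE = sum(1 / rl^2) / Nr, LRE = sum(rl^2) / Nr,
      GLN = gln / Nr, RLN = rln / Nr, RP = Nr / n_voxels,
      LGRE = sum(1 / lv^2) / Nr, HGRE = sum(lv^2) / Nr,
      SRLGE = sum(1 / (lv^2 * rl^2)) / Nr, SRHGE = sum(lv^2 / rl^2) / Nr,
      LRLGE = sum(rl^2 / lv^2) / Nr, LRHGE = sum(rl^2 * lv^2) / Nr)
  }
  colnames(feats) <- c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
                       "SRLGE", "SRHGE", "LRLGE", "LRHGE")
  colMeans(feats)
}

# --- wavelet ---------------------------------------------------------------
# Direct separable circular correlation with explicit modular arithmetic:
# y[i,j,k] = sum_{a,b,c} f1[a] f2[b] f3[c] x[w1(i+a-c), w2(j+b-c), w3(k+c-c)]
conv3_oracle <- function(x, f1, f2, f3) {
  d <- dim(x)
  ctr <- ceiling(length(f1) / 2)   # all three filters share length 6
  wrap <- function(i, n) ((i - 1) %% n) + 1
  y <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    acc <- 0
    for (a in seq_along(f1)) for (b in seq_along(f2)) for (cc in seq_along(f3)) {
      acc <- acc + f1[a] * f2[b] * f3[cc] *
        x[wrap(i + a - ctr, d[1]), wrap(j + b - ctr, d[2]),
          wrap(k + cc - ctr, d[3])]
    }
    y[i, j, k] <- acc
  }
  y
}

# --- LASSO -----------------------------------------------------------------
# Proximal-gradient (ISTA) solver for the mean-logistic-loss LASSO with
# unpenalized intercept; run to a much tighter tolerance than the package
# fit. Independent of glmnet's coordinate descent.
lasso_ista_oracle <- function(X, y01, lam, iters = 200000, step = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(step)) step <- 4 / max(colSums(X^2) / n) / p  # conservative
  beta <- rep(0, p); b0 <- 0
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (it in seq_len(iters)) {
    eta <- b0 + X %*% beta
    mu <- 1 / (1 + exp(-eta))
    grad <- as.vector(crossprod(X, mu - y01)) / n
    g0 <- mean(mu - y01)
    beta_new <- soft(beta - step * grad, step * lam)
    b0_new <- b0 - step * g0
    if (max(abs(c(beta_new - beta, b0_new - b0))) < 1e-10 * step) {
      beta <- beta_new; b0 <- b0_new
      break
    }
    beta <- beta_new; b0 <- b0_new
  }
  list(beta = as.vector(beta), intercept = b0)
}

# --- AUC -------------------------------------------------------------------
# Trapezoidal integration of the empirical ROC curve over all thresholds.
auc_trapezoid_oracle <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pos <- labels == "PD"
  tpr <- c(0, sapply(thr, function(t) mean(scores[pos] >= t)), 1)
  fpr <- c(0, sapply(thr, function(t) mean(scores[!pos] >= t)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# --- two-point hard-margin SVM --------------------------------------------
# For two support vectors x1 (PD) and x2 (HC) with ||x1 - x2|| large
# enough that alpha = 2/||x1-x2||^2 <= C, the maximum-margin solution is
# w = 2 (x1 - x2) / ||x1 - x2||^2,  b = -w . (x1 + x2) / 2.
svm_two_point_oracle <- function(x1, x2) {
  dd <- sum((x1 - x2)^2)
  w <- 2 * (x1 - x2) / dd
  list(w = w, b = -sum(w * (x1 + x2)) / 2)
}
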