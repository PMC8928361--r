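#include <Rcpp.h>
using namespace Rcpp;

// The 13 unique 3D offset directions at distance 1 (one of each
// antipodal pair; symmetric accumulation covers the other half).
static const int DIRS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0},
  {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Gray-level co-occurrence counts for every region in one pass.
// `levels` holds the per-region discretized gray level (1..nbins) of each
// voxel, 0 outside any usable region; `region` holds the region label.
// Pairs are only counted between voxels of the same region. Counts are
// accumulated symmetrically and summed over the 13 directions.
// Returns an nbins x nbins x nregions array of raw counts.
// [[Rcpp::export]]
NumericVector cpp_glcm_all(IntegerVector levels, IntegerVector region,
                           int nx, int ny, int nz, int nbins, int nregions) {
  NumericVector out(static_cast<R_xlen_t>(nbins) * nbins * nregions);
  const int *lev = INTEGER(levels);
  const int *reg = INTEGER(region);
  const R_xlen_t per_reg = static_cast<R_xlen_t>(nbins) * nbins;

  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int v = lin(x, y, z, nx, ny);
        const int r = reg[v];
        if (r <= 0 || lev[v] <= 0) continue;
        const int a = lev[v] - 1;
        for (int k = 0; k < 13; ++k) {
          const int x2 = x + DIRS[k][0], y2 = y + DIRS[k][1], z2 = z + DIRS[k][2];
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          const int w = lin(x2, y2, z2, nx, ny);
          if (reg[w] != r || lev[w] <= 0) continue;
          const int b = lev[w] - 1;
          double *m = REAL(out) + per_reg * (r - 1);
          m[a + nbins * b] += 1.0;
          m[b + nbins * a] += 1.0;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nbins, nbins, nregions);
  return out;
}

// Gray-level run-length counts per direction for every region.
// A run is a maximal collinear sequence of voxels sharing one gray level,
// entirely inside one region. Returns nbins x maxrun x 13 x nregions.
// [[Rcpp::export]]
NumericVector cpp_glrlm_all(IntegerVector levels, IntegerVector region,
                            int nx, int ny, int nz, int nbins, int maxrun,
                            int nregions) {
  NumericVector out(static_cast<R_xlen_t>(nbins) * maxrun * 13 * nregions);
  const int *lev = INTEGER(levels);
  const int *reg = INTEGER(region);
  double *o = REAL(out);
  const R_xlen_t s_run = nbins;
  const R_xlen_t s_dir = static_cast<R_xlen_t>(nbins) * maxrun;
  const R_xlen_t s_reg = s_dir * 13;

  for (int k = 0; k < 13; ++k) {
    const int dx = DIRS[k][0], dy = DIRS[k][1], dz = DIRS[k][2];
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          const int v = lin(x, y, z, nx, ny);
          const int r = reg[v];
          if (r <= 0 || lev[v] <= 0) continue;
          const int l = lev[v];
          // run start iff the predecessor is absent or different
          const int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz) {
            const int p = lin(xp, yp, zp, nx, ny);
            if (reg[p] == r && lev[p] == l) continue;
          }
          int len = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (xn >= 0 && xn < nx && yn >= 0 && yn < ny &&
                 zn >= 0 && zn < nz) {
            const int w = lin(xn, yn, zn, nx, ny);
            if (reg[w] != r || lev[w] != l) break;
            ++len;
            xn += dx; yn += dy; zn += dz;
          }
          if (len > maxrun) len = maxrun;  // cannot occur when maxrun = max dim
          o[(l - 1) + s_run * (len - 1) + s_dir * k + s_reg * (r - 1)] += 1.0;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nbins, maxrun, 13, nregions);
  return out;
}

// 22 co-occurrence features per region from raw symmetric count matrices
// (nbins x nbins x nregions). Degenerate rules: zero marginal variance
// gives Correlation = 0; zero marginal entropy gives IMC1 = IMC2 = 0;
// regions with no pairs give NA.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_features(NumericVector counts, int nbins,
                                int nregions) {
  NumericMatrix out(nregions, 22);
  const double *cc = REAL(counts);
  std::vector<double> P(static_cast<size_t>(nbins) * nbins);
  std::vector<double> px(nbins), pxmy(nbins), pxpy(2 * nbins + 1);
  const double LOG2 = std::log(2.0);
  for (int r = 0; r < nregions; ++r) {
    const double *m = cc + static_cast<R_xlen_t>(nbins) * nbins * r;
    double tot = 0;
    for (int i = 0; i < nbins * nbins; ++i) tot += m[i];
    if (tot == 0) {
      for (int f = 0; f < 22; ++f) out(r, f) = NA_REAL;
      continue;
    }
    for (int i = 0; i < nbins * nbins; ++i) P[i] = m[i] / tot;
    std::fill(px.begin(), px.end(), 0.0);
    std::fill(pxmy.begin(), pxmy.end(), 0.0);
    std::fill(pxpy.begin(), pxpy.end(), 0.0);
    for (int j = 0; j < nbins; ++j)
      for (int i = 0; i < nbins; ++i) {
        const double p = P[i + nbins * j];
        px[i] += p;
        pxmy[std::abs(i - j)] += p;
        pxpy[i + j] += p;                 // index k-2 for k = i+j+2
      }
    double mu = 0, sig2 = 0, HX = 0;
    for (int i = 0; i < nbins; ++i) mu += (i + 1) * px[i];
    for (int i = 0; i < nbins; ++i) sig2 += (i + 1 - mu) * (i + 1 - mu) * px[i];
    for (int i = 0; i < nbins; ++i)
      if (px[i] > 0) HX -= px[i] * std::log(px[i]) / LOG2;
    double autoc = 0, cp = 0, cs = 0, ct = 0, contrast = 0, dissim = 0;
    double energy = 0, HXY = 0, hom1 = 0, hom2 = 0, idmn = 0, idn = 0;
    double invvar = 0, maxp = 0, jvar = 0, HXY1 = 0, HXY2 = 0;
    for (int j = 0; j < nbins; ++j)
      for (int i = 0; i < nbins; ++i) {
        const double p = P[i + nbins * j];
        const double ii = i + 1, jj = j + 1;
        const double d = ii - jj, s = ii + jj - 2 * mu;
        autoc += ii * jj * p;
        cp += s * s * s * s * p;
        cs += s * s * s * p;
        ct += s * s * p;
        contrast += d * d * p;
        dissim += std::fabs(d) * p;
        energy += p * p;
        if (p > 0) HXY -= p * std::log(p) / LOG2;
        hom1 += p / (1 + std::fabs(d));
        hom2 += p / (1 + d * d);
        idmn += p / (1 + d * d / (double)(nbins * nbins));
        idn += p / (1 + std::fabs(d) / nbins);
        if (i != j) invvar += p / (d * d);
        if (p > maxp) maxp = p;
        jvar += (ii - mu) * (ii - mu) * p;
        const double q = px[i] * px[j];
        if (q > 0) {
          const double lq = std::log(q) / LOG2;
          HXY1 -= p * lq;
          HXY2 -= q * lq;
        }
      }
    double de = 0, se = 0, sa = 0, sv = 0;
    for (int k = 0; k < nbins; ++k)
      if (pxmy[k] > 0) de -= pxmy[k] * std::log(pxmy[k]) / LOG2;
    for (int k = 0; k <= 2 * nbins; ++k) {
      if (pxpy[k] > 0) {
        sa += (k + 2) * pxpy[k];
        se -= pxpy[k] * std::log(pxpy[k]) / LOG2;
      }
    }
    for (int k = 0; k <= 2 * nbins; ++k)
      if (pxpy[k] > 0) sv += (k + 2 - sa) * (k + 2 - sa) * pxpy[k];
    const double corr = sig2 > 0 ? (autoc - mu * mu) / sig2 : 0.0;
    const double imc1 = HX > 0 ? (HXY - HXY1) / HX : 0.0;
    double imc2 = 0;
    if (HX > 0) {
      const double a = 1 - std::exp(-2 * (HXY2 - HXY));
      imc2 = a > 0 ? std::sqrt(a) : 0.0;
    }
    const double vals[22] = {autoc, cp, cs, ct, contrast, corr, de, dissim,
                             energy, HXY, hom1, hom2, imc1, imc2, idmn, idn,
                             invvar, maxp, sa, se, sv, jvar};
    for (int f = 0; f < 22; ++f) out(r, f) = vals[f];
  }
  return out;
}

// 11 run-length features per region: computed per direction from the
// nbins x maxrun x 13 x nregions count array, averaged over directions.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm_features(NumericVector rl, int nbins, int maxrun,
                                 NumericVector n_voxels, int nregions) {
  NumericMatrix out(nregions, 11);
  const double *a = REAL(rl);
  const R_xlen_t s_dir = static_cast<R_xlen_t>(nbins) * maxrun;
  const R_xlen_t s_reg = s_dir * 13;
  std::vector<double> lev_tot(nbins), run_tot(maxrun);
  for (int r = 0; r < nregions; ++r) {
    double acc[11] = {0};
    bool any = false;
    for (int k = 0; k < 13; ++k) {
      const double *m = a + s_reg * r + s_dir * k;
      double Nr = 0;
      for (R_xlen_t i = 0; i < s_dir; ++i) Nr += m[i];
      if (Nr == 0) continue;               // cannot occur for nonempty regions
      any = true;
      std::fill(lev_tot.begin(), lev_tot.end(), 0.0);
      std::fill(run_tot.begin(), run_tot.end(), 0.0);
      double sre = 0, lre = 0, lgre = 0, hgre = 0, srlge = 0, srhge = 0,
             lrlge = 0, lrhge = 0;
      for (int j = 0; j < maxrun; ++j) {
        const double jj = (double)(j + 1), j2 = jj * jj;
        for (int i = 0; i < nbins; ++i) {
          const double c = m[i + nbins * j];
          if (c == 0) continue;
          const double ii = (double)(i + 1), i2 = ii * ii;
          lev_tot[i] += c;
          run_tot[j] += c;
          sre += c / j2;    lre += c * j2;
          lgre += c / i2;   hgre += c * i2;
          srlge += c / (i2 * j2); srhge += c * i2 / j2;
          lrlge += c * j2 / i2;   lrhge += c * j2 * i2;
        }
      }
      double gln = 0, rln = 0;
      for (int i = 0; i < nbins; ++i) gln += lev_tot[i] * lev_tot[i];
      for (int j = 0; j < maxrun; ++j) rln += run_tot[j] * run_tot[j];
      acc[0] += sre / Nr;  acc[1] += lre / Nr;
      acc[2] += gln / Nr;  acc[3] += rln / Nr;
      acc[4] += Nr / REAL(n_voxels)[r];
      acc[5] += lgre / Nr; acc[6] += hgre / Nr;
      acc[7] += srlge / Nr; acc[8] += srhge / Nr;
      acc[9] += lrlge / Nr; acc[10] += lrhge / Nr;
    }
    if (!any) {
      for (int f = 0; f < 11; ++f) out(r, f) = NA_REAL;
    } else {
      for (int f = 0; f < 11; ++f) out(r, f) = acc[f] / 13.0;
    }
  }
  return out;
}

// Equal-width per-region discretization: levels 1..nbins spanning each
// region's own [min, max]; constant regions map to level 1.
// [[Rcpp::export]]
IntegerVector cpp_discretize_regions(NumericVector arr, IntegerVector region,
                                     int nregions, int nbins) {
  const R_xlen_t n = arr.size();
  IntegerVector out(n);
  std::vector<double> lo(nregions, R_PosInf), hi(nregions, R_NegInf);
  const double *x = REAL(arr);
  const int *reg = INTEGER(region);
  for (R_xlen_t i = 0; i < n; ++i) {
    const int r = reg[i];
    if (r <= 0) continue;
    if (x[i] < lo[r - 1]) lo[r - 1] = x[i];
    if (x[i] > hi[r - 1]) hi[r - 1] = x[i];
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    const int r = reg[i];
    if (r <= 0) { out[i] = 0; continue; }
    const double w = hi[r - 1] - lo[r - 1];
    if (w <= 0) { out[i] = 1; continue; }
    int l = (int)std::floor((x[i] - lo[r - 1]) / w * nbins) + 1;
    if (l > nbins) l = nbins;
    out[i] = l;
  }
  return out;
}

// The 15 first-order statistics for every region of one (subband) volume.
// Population-variance convention; skewness/kurtosis of constant regions
// are 0; entropy/uniformity use the per-region equal-width histogram;
// median and the 90th percentile follow the linear-interpolation
// (type 7) quantile definition.
// [[Rcpp::export]]
NumericMatrix cpp_first_order_all(NumericVector arr, IntegerVector region,
                                  int nregions, int nbins) {
  NumericMatrix out(nregions, 15);
  std::fill(out.begin(), out.end(), NA_REAL);
  const R_xlen_t n = arr.size();
  const double *x = REAL(arr);
  const int *reg = INTEGER(region);
  std::vector<std::vector<double> > vals(nregions);
  for (R_xlen_t i = 0; i < n; ++i)
    if (reg[i] > 0) vals[reg[i] - 1].push_back(x[i]);
  std::vector<double> hist(nbins);
  for (int r = 0; r < nregions; ++r) {
    std::vector<double> &v = vals[r];
    const R_xlen_t m = (R_xlen_t)v.size();
    if (m == 0) continue;
    std::sort(v.begin(), v.end());
    const double mn = v.front(), mx = v.back();
    double s = 0, s2 = 0;
    for (R_xlen_t i = 0; i < m; ++i) { s += v[i]; s2 += v[i] * v[i]; }
    const double mu = s / m;
    double m2 = 0, m3 = 0, m4 = 0, madv = 0;
    for (R_xlen_t i = 0; i < m; ++i) {
      const double d = v[i] - mu;
      m2 += d * d; m3 += d * d * d; m4 += d * d * d * d;
      madv += std::fabs(d);
    }
    m2 /= m; m3 /= m; m4 /= m; madv /= m;
    const double med = (m % 2) ? v[(m - 1) / 2]
                               : 0.5 * (v[m / 2 - 1] + v[m / 2]);
    const double h = 0.9 * (m - 1);
    const R_xlen_t flo = (R_xlen_t)std::floor(h);
    const double p90 = (flo + 1 < m)
      ? v[flo] + (h - flo) * (v[flo + 1] - v[flo]) : v[m - 1];
    std::fill(hist.begin(), hist.end(), 0.0);
    const double w = mx - mn;
    for (R_xlen_t i = 0; i < m; ++i) {
      int l = (w > 0) ? (int)std::floor((v[i] - mn) / w * nbins) : 0;
      if (l >= nbins) l = nbins - 1;
      hist[l] += 1.0;
    }
    double unif = 0, ent = 0;
    const double LOG2 = std::log(2.0);
    for (int b = 0; b < nbins; ++b) {
      if (hist[b] == 0) continue;
      const double p = hist[b] / m;
      unif += p * p;
      ent -= p * std::log(p) / LOG2;
    }
    out(r, 0) = mn;                       // Minimum
    out(r, 1) = mx;                       // Maximum
    out(r, 2) = mu;                       // Mean
    out(r, 3) = med;                      // Median
    out(r, 4) = mx - mn;                  // Range
    out(r, 5) = m2;                       // Variance
    out(r, 6) = std::sqrt(m2);            // StandardDeviation
    out(r, 7) = m2 > 0 ? m3 / std::pow(m2, 1.5) : 0.0;  // Skewness
    out(r, 8) = m2 > 0 ? m4 / (m2 * m2) : 0.0;          // Kurtosis
    out(r, 9) = s2;                       // Energy
    out(r, 10) = std::sqrt(s2 / m);       // RootMeanSquare
    out(r, 11) = madv;                    // MeanAbsoluteDeviation
    out(r, 12) = unif;                    // Uniformity
    out(r, 13) = ent;                     // Entropy
    out(r, 14) = p90;                     // Percentile90
  }
  return out;
}
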