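#include <Rcpp.h>
using namespace Rcpp;

// Pooled-variance two-sample t statistic per column of a subjects x
// features matrix; `g1` flags group-1 rows. One pass per column.
// [[Rcpp::export]]
NumericVector cpp_ttest_t(NumericMatrix X, LogicalVector g1) {
  const int n = X.nrow(), p = X.ncol();
  int n1 = 0;
  for (int i = 0; i < n; ++i) if (g1[i]) ++n1;
  const int n2 = n - n1;
  NumericVector out(p);
  const double inv = 1.0 / n1 + 1.0 / n2;
  for (int j = 0; j < p; ++j) {
    const double *col = &X(0, j);
    double s1 = 0, q1 = 0, s2 = 0, q2 = 0;
    for (int i = 0; i < n; ++i) {
      const double v = col[i];
      if (g1[i]) { s1 += v; q1 += v * v; } else { s2 += v; q2 += v * v; }
    }
    const double m1 = s1 / n1, m2 = s2 / n2;
    const double v1 = (q1 - n1 * m1 * m1) / (n1 - 1);
    const double v2 = (q2 - n2 * m2 * m2) / (n2 - 1);
    const double sp2 = ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2);
    out[j] = (m1 - m2) / std::sqrt(sp2 * inv);
  }
  return out;
}
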