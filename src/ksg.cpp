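#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Chebyshev (max-norm) distance between rows i and j of m
static inline double cheb(const NumericMatrix& m, int i, int j) {
  double d = 0.0;
  for (int c = 0; c < m.ncol(); ++c) {
    double v = std::fabs(m(i, c) - m(j, c));
    if (v > d) d = v;
  }
  return d;
}

// Kraskov-Stoegbauer-Grassberger mutual information, algorithm 1.
// a, b: aligned sample matrices (one row per observation). Returns nats.
// Brute-force O(n^2) neighbour search; n up to ~1e4 is fine in compiled code.
// [[Rcpp::export(name = ".ksg_mi_nats")]]
double ksg_mi_nats(NumericMatrix a, NumericMatrix b, int k) {
  const int n = a.nrow();
  if (b.nrow() != n) stop("sample matrices must have equal row counts");
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n");

  std::vector<double> da(n), db(n), dj(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double ea = cheb(a, i, j);
      double eb = cheb(b, i, j);
      da[m] = ea;
      db[m] = eb;
      dj[m] = ea > eb ? ea : eb;
      ++m;
    }
    std::vector<double> tmp(dj.begin(), dj.begin() + m);
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    double eps = tmp[k - 1];
    int na = 0, nb = 0;
    for (int j = 0; j < m; ++j) {
      if (da[j] < eps) ++na;
      if (db[j] < eps) ++nb;
    }
    acc += R::digamma(na + 1.0) + R::digamma(nb + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}
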