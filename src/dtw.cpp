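#include <Rcpp.h>
using namespace Rcpp;

// Classical dynamic time warping: absolute-difference local cost, unit
// steps (match / insert / delete), no path-length normalisation.
// band < 0 means unconstrained; otherwise a Sakoe-Chiba corridor of
// half-width `band` around the diagonal (in index units).
// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector a, NumericVector b, int band) {
  const int n = a.size(), m = b.size();
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), inf);
    int jlo = 1, jhi = m;
    if (band >= 0) {
      // map i to the diagonal of a possibly rectangular grid
      double diag = (double)i * m / n;
      jlo = std::max(1, (int)std::ceil(diag - band));
      jhi = std::min(m, (int)std::floor(diag + band));
      if (jlo > jhi) continue;
    }
    for (int j = jlo; j <= jhi; ++j) {
      double cost = std::abs(a[i - 1] - b[j - 1]);
      double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = cost + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// All unordered pairwise DTW distances between rows of X.
// [[Rcpp::export]]
NumericMatrix dtw_pairwise_cpp(NumericMatrix X, int band) {
  const int n = X.nrow();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    NumericVector xi = X.row(i);
    for (int j = i + 1; j < n; ++j) {
      double d = dtw_cost_cpp(xi, X.row(j), band);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
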