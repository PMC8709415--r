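#include <Rcpp.h>
using namespace Rcpp;

// Kaufman-Rousseeuw PAM on a precomputed dissimilarity matrix.
// Dissimilarities are plain distances (not squared); the objective is the
// sum of each point's distance to its nearest medoid.

static double total_cost(const NumericMatrix& d, const std::vector<int>& med) {
  const int n = d.nrow();
  double td = 0.0;
  for (int j = 0; j < n; ++j) {
    double best = R_PosInf;
    for (size_t c = 0; c < med.size(); ++c)
      best = std::min(best, d(j, med[c]));
    td += best;
  }
  return td;
}

// Greedy BUILD: first medoid minimises total distance to all points; each
// subsequent medoid maximises the reduction in total dissimilarity.
// [[Rcpp::export]]
IntegerVector pam_build_cpp(NumericMatrix d, int k) {
  const int n = d.nrow();
  std::vector<int> med;
  std::vector<double> nearest(n, R_PosInf);
  std::vector<bool> is_med(n, false);

  // first medoid
  int best_i = 0;
  double best_td = R_PosInf;
  for (int i = 0; i < n; ++i) {
    double td = 0.0;
    for (int j = 0; j < n; ++j) td += d(j, i);
    if (td < best_td) { best_td = td; best_i = i; }
  }
  med.push_back(best_i);
  is_med[best_i] = true;
  for (int j = 0; j < n; ++j) nearest[j] = d(j, best_i);

  while ((int)med.size() < k) {
    int best_c = -1;
    double best_gain = -1.0;
    for (int c = 0; c < n; ++c) {
      if (is_med[c]) continue;
      double gain = 0.0;
      for (int j = 0; j < n; ++j)
        gain += std::max(0.0, nearest[j] - d(j, c));
      if (gain > best_gain) { best_gain = gain; best_c = c; }
    }
    med.push_back(best_c);
    is_med[best_c] = true;
    for (int j = 0; j < n; ++j)
      nearest[j] = std::min(nearest[j], d(j, best_c));
  }
  return wrap(med);  // 0-based
}

// SWAP local search: exchange a medoid for a non-medoid whenever it
// strictly decreases total dissimilarity (steepest descent). Returns the
// final medoids, the per-accepted-swap trace of the objective, and a
// convergence flag.
// [[Rcpp::export]]
List pam_swap_cpp(NumericMatrix d, IntegerVector medoids0, int max_iter) {
  const int n = d.nrow();
  const int k = medoids0.size();
  std::vector<int> med(medoids0.begin(), medoids0.end());
  std::vector<bool> is_med(n, false);
  for (int c = 0; c < k; ++c) is_med[med[c]] = true;

  std::vector<double> d1(n), d2(n);  // nearest / second-nearest medoid dist
  std::vector<int> a1(n);            // index (into med) of nearest medoid
  auto refresh = [&]() {
    for (int j = 0; j < n; ++j) {
      double b1 = R_PosInf, b2 = R_PosInf;
      int c1 = 0;
      for (int c = 0; c < k; ++c) {
        double dj = d(j, med[c]);
        if (dj < b1) { b2 = b1; b1 = dj; c1 = c; }
        else if (dj < b2) { b2 = dj; }
      }
      d1[j] = b1; d2[j] = b2; a1[j] = c1;
    }
  };
  refresh();

  std::vector<double> trace;
  trace.push_back(total_cost(d, med));
  bool converged = false;
  int iter = 0;
  const double eps = 1e-12;

  while (iter < max_iter) {
    ++iter;
    double best_delta = 0.0;
    int best_c = -1, best_h = -1;
    for (int c = 0; c < k; ++c) {
      for (int h = 0; h < n; ++h) {
        if (is_med[h]) continue;
        double delta = 0.0;
        for (int j = 0; j < n; ++j) {
          double djh = d(j, h);
          if (a1[j] == c) {
            delta += std::min(djh, d2[j]) - d1[j];
          } else if (djh < d1[j]) {
            delta += djh - d1[j];
          }
        }
        if (delta < best_delta) {
          best_delta = delta; best_c = c; best_h = h;
        }
      }
    }
    // guard against floating-point cycling on ~zero improvements
    if (best_c < 0 || best_delta > -eps * (1.0 + trace.back())) {
      converged = true;
      break;
    }
    is_med[med[best_c]] = false;
    med[best_c] = best_h;
    is_med[best_h] = true;
    refresh();
    trace.push_back(total_cost(d, med));
  }

  return List::create(
    _["medoids"] = wrap(med),  // 0-based
    _["trace"] = wrap(trace),
    _["n_iterations"] = iter,
    _["converged"] = converged
  );
}
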