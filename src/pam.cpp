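#include <Rcpp.h>
#include <limits>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Deterministic k-medoids on a precomputed distance matrix.
//
// BUILD: greedy cost-minimising medoid addition, ties broken by smallest
// row index.  SWAP: exact steepest descent -- every (medoid, non-medoid)
// exchange is scored each iteration and the best strictly cost-decreasing
// one is applied; ties go to the first pair in scan order (candidate index
// ascending, medoid slot ascending).  The per-iteration swap deltas are
// accumulated in O(n^2) using nearest/second-nearest medoid distances,
// which reproduces the naive O(k * n^2) scan exactly.

static void nearest_two(const NumericMatrix &d, const std::vector<int> &med,
                        std::vector<int> &nearest, std::vector<double> &dnear,
                        std::vector<double> &dsec) {
  const int n = d.nrow();
  const int k = (int)med.size();
  for (int j = 0; j < n; ++j) {
    double b1 = std::numeric_limits<double>::infinity();
    double b2 = b1;
    int arg = -1;
    for (int s = 0; s < k; ++s) {
      double v = d(j, med[s]);
      if (v < b1) { b2 = b1; b1 = v; arg = s; }
      else if (v < b2) { b2 = v; }
    }
    nearest[j] = arg; dnear[j] = b1; dsec[j] = b2;
  }
}

// [[Rcpp::export(name = ".pam_dist_cpp")]]
List pam_dist_cpp(NumericMatrix d, int k, double tol = 1e-12) {
  const int n = d.nrow();
  if (d.ncol() != n) stop("distance matrix must be square");
  if (k < 1 || k > n) stop("k must be in 1..n");

  std::vector<int> med;
  med.reserve(k);
  std::vector<bool> is_med(n, false);
  std::vector<double> dnear(n, std::numeric_limits<double>::infinity());

  // BUILD
  for (int t = 0; t < k; ++t) {
    int best = -1;
    double best_cost = std::numeric_limits<double>::infinity();
    for (int c = 0; c < n; ++c) {
      if (is_med[c]) continue;
      double cost = 0.0;
      for (int j = 0; j < n; ++j) {
        double v = d(j, c);
        double cur = dnear[j];
        cost += (v < cur) ? v : cur;
      }
      if (cost < best_cost) { best_cost = cost; best = c; }
    }
    med.push_back(best);
    is_med[best] = true;
    for (int j = 0; j < n; ++j) {
      double v = d(j, best);
      if (v < dnear[j]) dnear[j] = v;
    }
  }

  std::vector<int> nearest(n);
  std::vector<double> dn(n), ds(n);
  nearest_two(d, med, nearest, dn, ds);
  double cost = 0.0;
  for (int j = 0; j < n; ++j) cost += dn[j];

  std::vector<double> trace;
  trace.push_back(cost);

  // SWAP
  std::vector<double> corr(k);
  for (;;) {
    double best_delta = 0.0;
    int best_h = -1, best_s = -1;
    bool found = false;
    for (int h = 0; h < n; ++h) {
      if (is_med[h]) continue;
      double G = 0.0;
      std::fill(corr.begin(), corr.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        double dh = d(j, h);
        double g = (dh < dn[j]) ? dh - dn[j] : 0.0;
        G += g;
        double rep = (dh < ds[j]) ? dh : ds[j];
        corr[nearest[j]] += rep - dn[j] - g;
      }
      for (int s = 0; s < k; ++s) {
        double delta = G + corr[s];
        bool better = found ? (delta < best_delta) : (delta < -tol);
        if (better) { best_delta = delta; best_h = h; best_s = s; found = true; }
      }
    }
    if (!found) break;
    is_med[med[best_s]] = false;
    med[best_s] = best_h;
    is_med[best_h] = true;
    nearest_two(d, med, nearest, dn, ds);
    double new_cost = 0.0;
    for (int j = 0; j < n; ++j) new_cost += dn[j];
    cost = new_cost;
    trace.push_back(cost);
  }

  IntegerVector labels(n), medoids(k);
  for (int j = 0; j < n; ++j) labels[j] = nearest[j] + 1;
  for (int s = 0; s < k; ++s) medoids[s] = med[s] + 1;
  return List::create(_["medoids"] = medoids, _["labels"] = labels,
                      _["cost"] = cost, _["cost_trace"] = wrap(trace));
}
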