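#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Assign each row of X (n x p) to the nearest row of C (k x p) under the
// L1 (cityblock) distance. Returns 1-based labels and the summed distance.
// [[Rcpp::export]]
List l1_assign_cpp(NumericMatrix X, NumericMatrix C) {
  const int n = X.nrow(), p = X.ncol(), k = C.nrow();
  IntegerVector labels(n);
  NumericVector mind(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int best_j = 0;
    for (int j = 0; j < k; ++j) {
      double d = 0.0;
      for (int c = 0; c < p; ++c) {
        d += std::fabs(X(i, c) - C(j, c));
        if (d >= best) break;
      }
      if (d < best) { best = d; best_j = j; }
    }
    labels[i] = best_j + 1;
    mind[i] = best;
  }
  double obj = 0.0;
  for (int i = 0; i < n; ++i) obj += mind[i];
  return List::create(_["labels"] = labels, _["dist"] = mind,
                      _["objective"] = obj);
}

// Element-wise median of the rows of X within each label group (the
// L1-optimal centroid update). Empty groups yield NaN rows.
// [[Rcpp::export]]
NumericMatrix group_col_medians_cpp(NumericMatrix X, IntegerVector labels,
                                    int k) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix out(k, p);
  std::vector< std::vector<int> > members(k);
  for (int i = 0; i < n; ++i) members[labels[i] - 1].push_back(i);
  std::vector<double> buf;
  for (int j = 0; j < k; ++j) {
    const std::vector<int>& m = members[j];
    if (m.empty()) {
      for (int c = 0; c < p; ++c) out(j, c) = NA_REAL;
      continue;
    }
    const int sz = (int)m.size();
    buf.resize(sz);
    for (int c = 0; c < p; ++c) {
      for (int i = 0; i < sz; ++i) buf[i] = X(m[i], c);
      const int mid = sz / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (sz % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + mid);
        med = 0.5 * (lo + med);
      }
      out(j, c) = med;
    }
  }
  return out;
}
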