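#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact Euclidean k-nearest neighbors by brute force. Ties broken by cell
// index so the graph is fully deterministic. Self is excluded.
// X: cells x dims. Returns cells x k matrix of 1-based neighbor indices.
// [[Rcpp::export(name = ".cpp_knn")]]
IntegerMatrix cpp_knn(NumericMatrix X, int k) {
  const int n = X.nrow(), d = X.ncol();
  if (k >= n) stop("k must be smaller than the number of points");
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > cand(n - 1);
  for (int i = 0; i < n; ++i) {
    int c = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double s = 0.0;
      for (int t = 0; t < d; ++t) {
        double diff = X(i, t) - X(j, t);
        s += diff * diff;
      }
      cand[c++] = std::make_pair(s, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    // stable order among exact distance ties: sort the selected k by (dist, idx)
    std::sort(cand.begin(), cand.begin() + k);
    for (int t = 0; t < k; ++t) out(i, t) = cand[t].second + 1;
  }
  return out;
}
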