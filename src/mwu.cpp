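#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// One-sided Mann-Whitney U ("greater": x stochastically larger than y).
// U = sum_i [ #{y < x_i} + 0.5 * #{y == x_i} ].
//
// Exact branch: when n + m <= max_exact, the p-value is computed by
// exhaustive enumeration of all C(n+m, n) assignments of the pooled values
// to the two groups (ties handled exactly by the 0.5 weighting).
// Otherwise a normal approximation with continuity and tie correction is
// used; a fully tied pooled sample yields p = 1.

static double u_stat(const std::vector<double>& x, const std::vector<double>& ysorted) {
  double U = 0.0;
  for (double xi : x) {
    // ysorted ascending
    size_t lo = std::lower_bound(ysorted.begin(), ysorted.end(), xi) - ysorted.begin();
    size_t hi = std::upper_bound(ysorted.begin(), ysorted.end(), xi) - ysorted.begin();
    U += (double)lo + 0.5 * (double)(hi - lo);
  }
  return U;
}

// U from a pooled vector given indices of the x group (used in enumeration)
static double u_from_pool(const std::vector<double>& pool, const std::vector<int>& xidx,
                          const std::vector<char>& isx) {
  double U = 0.0;
  for (int i : xidx) {
    for (size_t j = 0; j < pool.size(); ++j) {
      if (isx[j]) continue;
      if (pool[j] < pool[i]) U += 1.0;
      else if (pool[j] == pool[i]) U += 0.5;
    }
  }
  return U;
}

static double exact_p(const std::vector<double>& x, const std::vector<double>& y) {
  const int n = (int)x.size(), m = (int)y.size(), N = n + m;
  std::vector<double> pool(x);
  pool.insert(pool.end(), y.begin(), y.end());
  std::vector<double> ys(y);
  std::sort(ys.begin(), ys.end());
  const double Uobs = u_stat(x, ys);

  // enumerate all C(N, n) subsets as the x group
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  long total = 0, ge = 0;
  std::vector<char> isx(N, 0);
  while (true) {
    std::fill(isx.begin(), isx.end(), 0);
    for (int i : idx) isx[i] = 1;
    double U = u_from_pool(pool, idx, isx);
    if (U >= Uobs - 1e-9) ++ge;
    ++total;
    // next combination
    int i = n - 1;
    while (i >= 0 && idx[i] == N - n + i) --i;
    if (i < 0) break;
    ++idx[i];
    for (int j = i + 1; j < n; ++j) idx[j] = idx[j - 1] + 1;
  }
  return (double)ge / (double)total;
}

// Normal approximation with tie correction + continuity correction.
// xs, ys must be sorted ascending; tie counts come from a merged scan.
static double approx_p(std::vector<double> xs, std::vector<double> ys) {
  const double n = (double)xs.size(), m = (double)ys.size(), N = n + m;
  std::sort(xs.begin(), xs.end());
  const double U = u_stat(xs, ys); // ys already sorted by caller

  // merged tie scan
  std::vector<double> all;
  all.reserve((size_t)N);
  std::merge(xs.begin(), xs.end(), ys.begin(), ys.end(), std::back_inserter(all));
  double tieterm = 0.0;
  size_t i = 0;
  while (i < all.size()) {
    size_t j = i;
    while (j < all.size() && all[j] == all[i]) ++j;
    double t = (double)(j - i);
    if (t > 1) tieterm += t * t * t - t;
    i = j;
  }
  double var = (n * m / 12.0) * ((N + 1.0) - tieterm / (N * (N - 1.0)));
  if (var <= 0) return 1.0; // all values tied
  double z = (U - n * m / 2.0 - 0.5) / std::sqrt(var);
  return R::pnorm(z, 0.0, 1.0, 0, 0); // upper tail
}

// [[Rcpp::export(name = ".cpp_mwu_greater")]]
double cpp_mwu_greater(NumericVector x, NumericVector y, int max_exact = 12) {
  if (x.size() == 0) stop("empty first sample");
  if (y.size() == 0) stop("empty second sample");
  std::vector<double> xs(x.begin(), x.end()), ys(y.begin(), y.end());
  if ((int)(xs.size() + ys.size()) <= max_exact) return exact_p(xs, ys);
  std::sort(ys.begin(), ys.end());
  return approx_p(xs, ys);
}

// Matrix driver: p-values for every (focal cell) x (gene) pair.
// expr: genes x cells matrix of normalized expression
// nbhd: (k+1) x nfocal matrix of 1-based cell indices (focal + neighbors)
// bg:   1-based background cell indices
// genes: 1-based row indices of the genes to test
// Returns nfocal x ngene matrix of one-sided p-values.
// [[Rcpp::export(name = ".cpp_call_pvals")]]
NumericMatrix cpp_call_pvals(NumericMatrix expr, IntegerMatrix nbhd,
                             IntegerVector bg, IntegerVector genes,
                             int max_exact = 12) {
  const int nf = nbhd.ncol(), k = nbhd.nrow(), ng = genes.size(), nb = bg.size();
  NumericMatrix out(nf, ng);
  std::vector<double> bgv(nb), xv(k);
  for (int g = 0; g < ng; ++g) {
    const int grow = genes[g] - 1;
    for (int b = 0; b < nb; ++b) bgv[b] = expr(grow, bg[b] - 1);
    std::sort(bgv.begin(), bgv.end());
    for (int c = 0; c < nf; ++c) {
      for (int i = 0; i < k; ++i) xv[i] = expr(grow, nbhd(i, c) - 1);
      if (k + nb <= max_exact) {
        std::vector<double> yv(bgv);
        out(c, g) = exact_p(xv, yv);
      } else {
        std::vector<double> xs(xv);
        std::vector<double> ys(bgv);
        out(c, g) = approx_p(xs, ys);
      }
    }
  }
  return out;
}
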