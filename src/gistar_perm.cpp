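#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Conditional-permutation pseudo-p-values for the Getis-Ord Gi* statistic.
//
// Under conditional permutation the focal value is held fixed and the k
// neighbor values are drawn without replacement from the remaining n-1
// values. Because the global mean, global SD, n and the (binary, equal
// count) weights are unchanged by the permutation, the permuted z is a
// strictly increasing function of the permuted weighted sum, so comparing
// |z_perm| >= |z_obs| reduces to comparing absolute deviations of the
// weighted sums from their null center xbar * W. The count is two-sided on
// the magnitude (the sign of the observed z decides hot vs cold downstream,
// not the p-value), which keeps the test calibrated at its nominal level
// under exchangeable surfaces.
//
// Draw scheme (pinned so a plain-R oracle can replicate it exactly under a
// shared seed): units in index order; for each unit, n_perm permutations;
// each permutation performs a k-step partial Fisher-Yates on the index
// vector 0..m-1 of the pool (the other m = n-1 values), consuming exactly
// one R-core uniform per step via unif_rand().
//
// nb: n x k matrix of 1-based neighbor indices (self excluded).
// valid: per-unit flag; 0 or NA -> NA p-value (degenerate z).
// center: xbar * (k + 1), the null expectation of the weighted sum.
// Returns (count of as-or-more-extreme permutations + 1) / (n_perm + 1).
// [[Rcpp::export]]
NumericVector rcpp_gi_perm_p(NumericVector x, IntegerMatrix nb,
                             IntegerVector valid, double center,
                             int n_perm) {
  const int n = x.size();
  const int k = nb.ncol();
  const int m = n - 1;
  NumericVector p(n);
  std::vector<double> pool(m);
  std::vector<int> idx(m);
  std::vector<int> pos(k), other(k);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    if (valid[i] == NA_INTEGER || valid[i] == 0) {
      // consume the same number of uniforms regardless, keeping downstream
      // units' draws independent of this unit's degeneracy
      for (int b = 0; b < n_perm; ++b)
        for (int t = 0; t < k; ++t) unif_rand();
      p[i] = NA_REAL;
      continue;
    }
    int q = 0;
    for (int j = 0; j < n; ++j) if (j != i) pool[q++] = x[j];
    for (int j = 0; j < m; ++j) idx[j] = j;
    double obs = x[i];
    for (int t = 0; t < k; ++t) obs += x[nb(i, t) - 1];
    const double obs_dev = std::abs(obs - center);
    int count = 0;
    for (int b = 0; b < n_perm; ++b) {
      double s = x[i];
      for (int t = 0; t < k; ++t) {
        int r = t + (int)(unif_rand() * (m - t));
        if (r >= m) r = m - 1; // guard against u == 1.0
        pos[t] = t; other[t] = r;
        int tmp = idx[t]; idx[t] = idx[r]; idx[r] = tmp;
        s += pool[idx[t]];
      }
      if (std::abs(s - center) >= obs_dev) ++count;
      for (int t = k - 1; t >= 0; --t) { // undo swaps
        int tmp = idx[pos[t]]; idx[pos[t]] = idx[other[t]]; idx[other[t]] = tmp;
      }
    }
    p[i] = (count + 1.0) / (n_perm + 1.0);
  }
  return p;
}
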