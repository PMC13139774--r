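// Fused Adam kernel for the hand-rolled training loops. Parameters,
// gradients and the two moment accumulators are passed as flat lists of
// leaf vectors (same tree order); the update runs in place, so the caller
// owns all four trees exclusively.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
void adam_update_tree_cpp(List th, List g, List m, List v, int t,
                          double lr, double beta1, double beta2, double eps) {
  int L = th.size();
  if (g.size() != L || m.size() != L || v.size() != L)
    stop("adam_update_tree_cpp: leaf-count mismatch");
  double alpha = lr * std::sqrt(1.0 - std::pow(beta2, (double)t)) /
                 (1.0 - std::pow(beta1, (double)t));
  for (int l = 0; l < L; ++l) {
    NumericVector thl = th[l], gl = g[l], ml = m[l], vl = v[l];
    R_xlen_t n = thl.size();
    if (gl.size() != n || ml.size() != n || vl.size() != n)
      stop("adam_update_tree_cpp: leaf length mismatch at leaf %d", l + 1);
    double *pt = REAL(thl), *pg = REAL(gl), *pm = REAL(ml), *pv = REAL(vl);
    for (R_xlen_t i = 0; i < n; ++i) {
      double mi = beta1 * pm[i] + (1.0 - beta1) * pg[i];
      double vi = beta2 * pv[i] + (1.0 - beta2) * pg[i] * pg[i];
      pm[i] = mi;
      pv[i] = vi;
      pt[i] -= alpha * mi / (std::sqrt(vi) + eps);
    }
  }
}
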