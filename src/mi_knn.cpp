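#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Ross mixed discrete-continuous mutual information estimator for one
// continuous variable x against a discrete label y, k nearest neighbors,
// Chebyshev (= absolute, in 1-D) distance.
//
// For each point i: d_i = distance to its k-th nearest neighbor among
// points sharing its label; m_i = number of points (any label, self
// included) at distance strictly less than d_i. Then
//   I = digamma(N) - <digamma(N_yi)> + digamma(k) - <digamma(m_i)>.
// Values are assumed jittered so that distances are almost surely distinct.
// [[Rcpp::export(name = ".mi_knn_cpp")]]
double mi_knn_cpp(NumericVector x, IntegerVector y, int k) {
  const int n = x.size();
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());

  // group indices per label, values sorted within each label
  std::map<int, std::vector<double> > groups;
  for (int i = 0; i < n; ++i) groups[y[i]].push_back(x[i]);
  for (auto &g : groups) std::sort(g.second.begin(), g.second.end());

  double sum_psi_m = 0.0, sum_psi_nx = 0.0;
  for (auto &g : groups) {
    const std::vector<double> &s = g.second;
    const int nc = (int)s.size();
    if (nc <= k)
      stop("a label class has <= k members; lower k");
    for (int i = 0; i < nc; ++i) {
      // k-th nearest same-label neighbor via two-pointer expansion
      int l = i - 1, r = i + 1, taken = 0;
      double d = 0.0;
      while (taken < k) {
        double dl = (l >= 0) ? s[i] - s[l] : R_PosInf;
        double dr = (r < nc) ? s[r] - s[i] : R_PosInf;
        if (dl <= dr) { d = dl; --l; } else { d = dr; ++r; }
        ++taken;
      }
      // strict count over the full sample: x_j in (s[i]-d, s[i]+d)
      std::vector<double>::const_iterator lo =
          std::upper_bound(xs.begin(), xs.end(), s[i] - d);
      std::vector<double>::const_iterator hi =
          std::lower_bound(xs.begin(), xs.end(), s[i] + d);
      int m = (int)(hi - lo);
      if (m < 1) m = 1;
      sum_psi_m += R::digamma((double)m);
      sum_psi_nx += R::digamma((double)nc);
    }
  }
  double mi = R::digamma((double)n) - sum_psi_nx / n +
              R::digamma((double)k) - sum_psi_m / n;
  return mi;
}
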