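#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Dynamic-time-warping alignment of two scalar series with absolute
// difference as the local cost. Fills the accumulated-cost matrix with
// steps (i-1,j-1), (i-1,j), (i,j-1) and backtracks one optimal coupling,
// preferring the diagonal step on ties (then the step in the longer-index
// direction deterministically).
// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("dtw requires non-empty series");
  std::vector<double> D((size_t)n * m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = std::fabs(a[i] - b[j]);
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else if (i == 0) best = D[(size_t)i * m + (j - 1)];
      else if (j == 0) best = D[(size_t)(i - 1) * m + j];
      else {
        best = D[(size_t)(i - 1) * m + (j - 1)];
        double up = D[(size_t)(i - 1) * m + j];
        double lf = D[(size_t)i * m + (j - 1)];
        if (up < best) best = up;
        if (lf < best) best = lf;
      }
      D[(size_t)i * m + j] = c + best;
    }
  }
  // backtrack
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i); pj.push_back(j);
  while (i > 0 || j > 0) {
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      double dg = D[(size_t)(i - 1) * m + (j - 1)];
      double up = D[(size_t)(i - 1) * m + j];
      double lf = D[(size_t)i * m + (j - 1)];
      if (dg <= up && dg <= lf) { --i; --j; }
      else if (up <= lf) { --i; }
      else { --j; }
    }
    pi.push_back(i); pj.push_back(j);
  }
  const int k = pi.size();
  IntegerMatrix pairs(k, 2);
  for (int r = 0; r < k; ++r) {
    pairs(r, 0) = pi[k - 1 - r];
    pairs(r, 1) = pj[k - 1 - r];
  }
  return List::create(_["pairs"] = pairs,
                      _["distance"] = D[(size_t)(n - 1) * m + (m - 1)]);
}
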