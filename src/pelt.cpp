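#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Optimal partitioning for a mean-shift model with unit variance and a
// bounded maximum segment length. Segment cost is -(segment sum)^2 / length
// (residual sum of squares minus the segmentation-invariant sum of squares);
// one penalty unit is paid per segment. Bounding the lookback window makes
// the recursion O(n * maxLen): exact for any event shorter than maxLen,
// while long change-free stretches are represented as chains of maxLen
// segments with near-zero mean (harmless, since only segments crossing a
// mean-z threshold become calls and calls are capped at 200 probes).
// Returns the 1-based end index of every segment (last element = n).
// [[Rcpp::export]]
IntegerVector segment_meanshift(NumericVector z, double penalty, int maxLen) {
  int n = z.size();
  if (n == 0) stop("empty track");
  if (maxLen < 1) stop("maxLen must be >= 1");
  std::vector<double> S(n + 1, 0.0);
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + z[i];
  std::vector<double> F(n + 1, 0.0);
  std::vector<int> prev(n + 1, 0);
  F[0] = -penalty;
  for (int t = 1; t <= n; ++t) {
    double best = R_PosInf;
    int arg = std::max(0, t - maxLen);
    for (int s = std::max(0, t - maxLen); s < t; ++s) {
      double d = S[t] - S[s];
      double v = F[s] - d * d / (t - s) + penalty;
      if (v < best) { best = v; arg = s; }
    }
    F[t] = best;
    prev[t] = arg;
  }
  std::vector<int> ends;
  for (int t = n; t > 0; t = prev[t]) ends.push_back(t);
  std::reverse(ends.begin(), ends.end());
  return wrap(ends);
}
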