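#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact optimal partitioning for penalized least-squares changepoint
// detection: minimize sum of within-segment squared error plus
// penalty * (number of segments), subject to a minimum segment size.
// O(n^2) dynamic programme over segment end positions.
// [[Rcpp::export(name = ".dpSegment")]]
List dpSegment(NumericVector y, double penalty, int minSize) {
  const int n = y.size();
  if (n < 1) stop("empty profile");
  if (minSize < 1) stop("minSize must be >= 1");
  std::vector<double> cs(n + 1, 0.0), css(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + y[i];
    css[i + 1] = css[i] + y[i] * y[i];
  }
  std::vector<double> F(n + 1, R_PosInf);
  std::vector<int> prev(n + 1, -1);
  F[0] = 0.0;
  for (int i = minSize; i <= n; ++i) {
    double best = R_PosInf;
    int bestj = -1;
    for (int j = 0; j <= i - minSize; ++j) {
      if (!R_FINITE(F[j])) continue;
      const int len = i - j;
      const double s = cs[i] - cs[j];
      const double sse = css[i] - css[j] - s * s / len;
      const double c = F[j] + sse + penalty;
      if (c < best) {
        best = c;
        bestj = j;
      }
    }
    F[i] = best;
    prev[i] = bestj;
  }
  if (!R_FINITE(F[n]))
    return List::create(_["ends"] = IntegerVector::create(n),
                        _["cost"] = NA_REAL, _["feasible"] = false);
  std::vector<int> ends;
  for (int i = n; i > 0; i = prev[i]) ends.push_back(i);
  std::reverse(ends.begin(), ends.end());
  return List::create(_["ends"] = wrap(ends), _["cost"] = F[n],
                      _["feasible"] = true);
}
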