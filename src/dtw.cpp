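#include <Rcpp.h>
using namespace Rcpp;

// Classic dynamic-programming DTW with the symmetric1 step pattern
// (match/insert/delete, unit weights) and Euclidean (absolute) local
// cost. Quadratic in series length, so it lives in compiled code.
// [[Rcpp::export(name = ".dtw_dp")]]
double dtw_dp(NumericVector x, NumericVector y) {
  const int n = x.size(), m = y.size();
  std::vector<double> prev(m), curr(m);
  for (int j = 0; j < m; ++j) {
    double c = std::abs(x[0] - y[j]);
    prev[j] = (j == 0) ? c : prev[j - 1] + c;
  }
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = std::abs(x[i] - y[j]);
      if (j == 0) {
        curr[j] = prev[j] + c;
      } else {
        double best = std::min(std::min(prev[j], curr[j - 1]), prev[j - 1]);
        curr[j] = best + c;
      }
    }
    std::swap(prev, curr);
  }
  return prev[m - 1];
}
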