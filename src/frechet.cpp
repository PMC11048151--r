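// Discrete Frechet distance between two amplitude sequences, computed with
// the classic dynamic program over monotone couplings:
//   ca(i,j) = max(d(i,j), min(ca(i-1,j), ca(i-1,j-1), ca(i,j-1)))
// with d the absolute amplitude difference.  O(n*m) time, O(m) memory.

#include <Rcpp.h>
#include <cmath>
#include <vector>

// [[Rcpp::export(name = ".frechet_dp")]]
double frechet_dp_cpp(Rcpp::NumericVector a, Rcpp::NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) Rcpp::stop("frechet_distance needs non-empty inputs");
  std::vector<double> prev(m), cur(m);
  for (int j = 0; j < m; ++j) {
    double d = std::fabs(a[0] - b[j]);
    prev[j] = (j == 0) ? d : std::max(prev[j - 1], d);
  }
  for (int i = 1; i < n; ++i) {
    cur[0] = std::max(prev[0], std::fabs(a[i] - b[0]));
    for (int j = 1; j < m; ++j) {
      double reach = std::min(prev[j], std::min(prev[j - 1], cur[j - 1]));
      cur[j] = std::max(reach, std::fabs(a[i] - b[j]));
    }
    prev.swap(cur);
  }
  return prev[m - 1];
}
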