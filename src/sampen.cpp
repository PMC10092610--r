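#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman & Moorman counting):
// over the N - m template start points, B counts pairs (i < j) whose
// m-length templates lie within Chebyshev distance r, A the same for
// m+1-length templates. Self-matches are excluded by construction.
// Early-abort inner comparison keeps the O(N^2) scan cheap.
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // template count for both lengths
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (i + m < n && j + m < n && std::fabs(x[i + m] - x[j + m]) <= r) {
        A += 1.0;
      }
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}
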