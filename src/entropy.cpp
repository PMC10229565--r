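#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman-Moorman convention).
//
// Counts unordered pairs (i < j) among the first N - m templates whose
// length-m vectors lie within Chebyshev distance r (B), and, for the same
// template set, whose length-(m+1) extensions also lie within r (A).
// Self-matches are excluded by construction.
//
// [[Rcpp::export]]
List sampen_counts(NumericVector x, int m, double r) {
  const int N = x.size();
  const int nt = N - m;  // number of templates with an (m+1)-th point
  if (nt < 2 || m < 1 || r <= 0.0)
    stop("sample entropy needs N > m + 1 and r > 0");
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool within = true;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) { within = false; break; }
      }
      if (within) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}
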