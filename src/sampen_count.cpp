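#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match pair counts for sample entropy.
//
// Both the length-m and length-(m+1) counts run over the same template
// index range i = 0 .. N-m-1 (the Richman-Moorman convention), so the
// ratio A/B compares like with like. A pair (i, j), i < j, matches at
// length L when the Chebyshev distance between the two templates is
// <= tol (inclusive). Self-matches (i == j) are never counted.
//
// Returns c(b_pairs, a_pairs, n_templates) as doubles (counts can exceed
// .Machine$integer.max for long series).
// [[Rcpp::export(name = ".count_matches_cpp")]]
NumericVector count_matches_cpp(NumericVector x, int m, double tol) {
  const int n = x.size();
  const int nt = n - m;  // templates of length m+1 exist for i = 0..nt-1
  double b = 0.0, a = 0.0;
  const double *p = REAL(x);
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(p[i + k] - p[j + k]) > tol) { match = false; break; }
      }
      if (match) {
        b += 1.0;
        if (std::fabs(p[i + m] - p[j + m]) <= tol) a += 1.0;
      }
    }
  }
  return NumericVector::create(b, a, (double)nt);
}
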