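#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template match counts for sample entropy.
//
// Over all template pairs i < j drawn from the first n - m positions (so
// the (m+1)-point extension exists for both), counts
//   B: pairs whose m-point templates match (Chebyshev distance < r), and
//   A: matching pairs whose (m+1)-th points also lie within r.
// Self-matches are excluded by construction. SE = -log(A/B).
//
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of template start positions
  double A = 0.0, B = 0.0;
  if (m == 2) {          // hot path: the default template length
    const double *p = x.begin();
    for (int i = 0; i < nt - 1; ++i) {
      const double xi0 = p[i], xi1 = p[i + 1], xi2 = p[i + 2];
      for (int j = i + 1; j < nt; ++j) {
        if (std::abs(xi0 - p[j]) < r && std::abs(xi1 - p[j + 1]) < r) {
          B += 1.0;
          if (std::abs(xi2 - p[j + 2]) < r) A += 1.0;
        }
      }
    }
    return NumericVector::create(A, B);
  }
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) >= r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::abs(x[i + m] - x[j + m]) < r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}
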