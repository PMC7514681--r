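#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy.
//
// Counts, over template start indices i < j in 1..(n - m), the pairs whose
// length-m templates match under the Chebyshev (max-abs) distance with
// tolerance r (B), and among those, the pairs whose length-(m+1) templates
// also match (A).  Self-matches are excluded by construction (i < j).  Both
// counts use the same set of n - m template positions, the Richman-Moorman
// convention, so A/B is a conditional probability.
//
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  if (m < 1) stop("m must be >= 1");
  if (!(r > 0)) stop("r must be > 0");
  if (n <= m + 1) stop("series too short for m");

  const int nt = n - m;  // number of template positions
  double A = 0.0, B = 0.0;
  const double *p = REAL(x);

  for (int i = 0; i < nt - 1; ++i) {
    const double *xi = p + i;
    for (int j = i + 1; j < nt; ++j) {
      const double *xj = p + j;
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(xi[k] - xj[k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (std::abs(xi[m] - xj[m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(Named("A") = A, Named("B") = B);
}
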