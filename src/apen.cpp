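#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Approximate entropy, classic formulation: self-matches included,
// non-strict Chebyshev tolerance. Counts matches for dimensions m and m+1
// in a single pass over vector pairs: the (m+1)-dimensional distance
// exceeds r whenever the m-dimensional prefix already does, so the extra
// coordinate is only examined for pairs that match at dimension m.
//
// Returns phi_m, phi_m1 and apen = phi_m - phi_m1.
// [[Rcpp::export]]
List apen_core(NumericVector x, int m, double r, int tau) {
  const int n = x.size();
  const int M1 = n - (m - 1) * tau;  // embedding vectors at dimension m
  const int M2 = n - m * tau;        // embedding vectors at dimension m + 1
  if (M2 < 1) stop("series too short for the given (m, tau)");

  std::vector<int> c1(M1, 1), c2(M2, 1);  // self-match included

  const double *u = REAL(x);
  for (int i = 0; i < M1; ++i) {
    for (int j = i + 1; j < M1; ++j) {
      bool match_m = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(u[i + k * tau] - u[j + k * tau]) > r) {
          match_m = false;
          break;
        }
      }
      if (!match_m) continue;
      ++c1[i];
      ++c1[j];
      if (j < M2 && std::fabs(u[i + m * tau] - u[j + m * tau]) <= r) {
        ++c2[i];
        ++c2[j];
      }
    }
  }

  double phi1 = 0.0, phi2 = 0.0;
  for (int i = 0; i < M1; ++i) phi1 += std::log((double)c1[i] / M1);
  for (int i = 0; i < M2; ++i) phi2 += std::log((double)c2[i] / M2);
  phi1 /= M1;
  phi2 /= M2;

  return List::create(_["phi_m"] = phi1, _["phi_m1"] = phi2,
                      _["apen"] = phi1 - phi2);
}
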