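#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Step-down maxT counting for the sign-flip permutation null.
//
// X:    probes x arrays matrix of oriented M values, NAs replaced by 0
// nn:   per-probe count of non-missing arrays (>= 2)
// ss:   per-probe sum of squares over non-missing cells
// S:    arrays x B matrix of +/-1 sign columns (one column per permutation)
// ord:  0-based probe indices in ascending order of observed |t|
// tabs: observed |t| per probe (zero-variance probes encoded as DBL_MAX)
//
// Returns, per probe i, the number of sign columns b whose step-down
// successive maximum max_{j: |t_j| <= |t_i|} |t_b(j)| reaches tabs[i].
// Observed |t| per probe under the identity sign assignment, computed with
// bitwise the same arithmetic as the permutation loop so that equality at
// the identity flip is exact.
// [[Rcpp::export(name = ".perm_obs_t")]]
NumericVector perm_obs_t(NumericMatrix X, IntegerVector nn, NumericVector ss) {
  const int p = X.nrow(), n = X.ncol();
  NumericVector out(p);
  for (int j = 0; j < p; ++j) {
    double dot = 0.0;
    for (int a = 0; a < n; ++a) dot += X(j, a);
    const double nj = (double) nn[j];
    const double m = dot / nj;
    const double v = (ss[j] - nj * m * m) / (nj - 1.0);
    out[j] = (v <= 1e-300) ? DBL_MAX : std::fabs(m) / std::sqrt(v / nj);
  }
  return out;
}

// [[Rcpp::export(name = ".perm_stepdown_counts")]]
IntegerVector perm_stepdown_counts(NumericMatrix X, IntegerVector nn,
                                   NumericVector ss, IntegerMatrix S,
                                   IntegerVector ord, NumericVector tabs) {
  const int p = X.nrow(), n = X.ncol(), B = S.ncol();
  if (S.nrow() != n) stop("sign matrix does not match array count");
  IntegerVector counts(p);
  std::vector<double> srow(n);
  for (int b = 0; b < B; ++b) {
    for (int a = 0; a < n; ++a) srow[a] = (double) S(a, b);
    double runmax = -1.0;
    for (int k = 0; k < p; ++k) {
      const int j = ord[k];
      double dot = 0.0;
      for (int a = 0; a < n; ++a) dot += X(j, a) * srow[a];
      const double nj = (double) nn[j];
      const double m = dot / nj;
      const double v = (ss[j] - nj * m * m) / (nj - 1.0);
      double t;
      if (v <= 1e-300) {
        t = DBL_MAX;
      } else {
        t = std::fabs(m) / std::sqrt(v / nj);
      }
      if (t > runmax) runmax = t;
      if (runmax >= tabs[j]) counts[j] += 1;
    }
  }
  return counts;
}
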