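#include <Rcpp.h>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo recursion on a
// topologically sorted pedigree. sire/dam are 1-based positions into the
// sorted pedigree, 0 = unknown. Unknown parents are base animals: their
// "F" enters the within-family variance term as -1 so that
// d_i = 0.5 - 0.25 (F_s + F_d) reduces to 1 (both unknown) or
// 0.75 - 0.25 F_s (one known).
//
// For animal i the diagonal a_ii = sum_j L_ij^2 d_j is accumulated by a
// backward sweep that pushes generation-flow coefficients L onto parents;
// F_i = a_ii - 1.
// [[Rcpp::export]]
NumericVector inbreeding_ml(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> d(n + 1, 0.0), L(n + 1, 0.0);

  for (int i = 1; i <= n; ++i) {
    int s = sire[i - 1], dd = dam[i - 1];
    double Fs = (s > 0) ? F[s - 1] : -1.0;
    double Fd = (dd > 0) ? F[dd - 1] : -1.0;
    d[i] = 0.5 - 0.25 * (Fs + Fd);
    if (s == 0 && dd == 0) {
      F[i - 1] = 0.0;
      continue;
    }
    L[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 1; --j) {
      double lj = L[j];
      if (lj != 0.0) {
        aii += lj * lj * d[j];
        int sj = sire[j - 1], dj = dam[j - 1];
        if (sj > 0) L[sj] += 0.5 * lj;
        if (dj > 0) L[dj] += 0.5 * lj;
        L[j] = 0.0;
      }
    }
    F[i - 1] = aii - 1.0;
  }
  return F;
}
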