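#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Template match counts for sample entropy.
// B counts unordered pairs i < j (i, j <= N - m) of length-m templates whose
// Chebyshev distance is strictly below r; A counts the subset of those pairs
// that still match when the templates are extended to length m + 1.
// Self-matches are excluded by construction.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of length-m templates that extend to m+1
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) >= r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) < r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// Mean fuzzy similarities phi_m and phi_{m+1}.
// Both use the N - m templates whose (m+1)-extension exists; each template
// has its own mean removed before the Chebyshev distance is taken, and the
// similarity is exp(-(d / r)^p). The mean is over ordered pairs i != j,
// which equals the unordered-pair mean because the similarity is symmetric.
// [[Rcpp::export]]
NumericVector fuzzen_phi(NumericVector x, int m, double r, double p) {
  const int n = x.size();
  const int nt = n - m;
  // window means for lengths m and m+1
  std::vector<double> mu_m(nt), mu_m1(nt);
  {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += x[k];
    for (int i = 0; i < nt; ++i) {
      mu_m[i] = s / m;
      if (i + 1 < nt) s += x[i + m] - x[i];
    }
    s = 0.0;
    for (int k = 0; k < m + 1; ++k) s += x[k];
    for (int i = 0; i < nt; ++i) {
      mu_m1[i] = s / (m + 1);
      if (i + 1 < nt) s += x[i + m + 1] - x[i];
    }
  }
  double sum_m = 0.0, sum_m1 = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dm = 0.0, dm1 = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs((x[i + k] - mu_m[i]) - (x[j + k] - mu_m[j]));
        if (d > dm) dm = d;
      }
      for (int k = 0; k < m + 1; ++k) {
        double d = std::fabs((x[i + k] - mu_m1[i]) - (x[j + k] - mu_m1[j]));
        if (d > dm1) dm1 = d;
      }
      sum_m  += std::exp(-std::pow(dm  / r, p));
      sum_m1 += std::exp(-std::pow(dm1 / r, p));
    }
  }
  const double npairs = 0.5 * double(nt) * double(nt - 1);
  return NumericVector::create(sum_m / npairs, sum_m1 / npairs);
}
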