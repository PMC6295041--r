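#include <Rcpp.h>
using namespace Rcpp;

// Meuwissen & Luo (1992) recursion for inbreeding coefficients.
// Pedigree must be topologically sorted with ids 1..n; 0 = unknown parent.
// F[0] = -1 encodes the unknown-parent convention so that the
// Mendelian-sampling variance d_i = 0.5 - 0.25 (F_s + F_d) comes out as
// 1 (both unknown) or 0.75 - 0.25 F_known (one unknown) automatically.
// [[Rcpp::export(name = ".ml_inbreeding")]]
NumericVector ml_inbreeding(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  std::vector<double> F(n + 1, 0.0), L(n + 1, 0.0), D(n + 1, 0.0);
  std::vector<int> point(n + 1, 0);
  F[0] = -1.0;
  for (int i = 1; i <= n; ++i) {
    const int is = sire[i - 1], id = dam[i - 1];
    if (is > i || id > i)
      stop("pedigree is not sorted: parents must precede offspring");
    D[i] = 0.5 - 0.25 * (F[is] + F[id]);
    if (is == 0 || id == 0) { F[i] = 0.0; continue; }
    double fi = -1.0;
    L[i] = 1.0;
    int j = i;
    while (j != 0) {
      int k = j;
      const double r = 0.5 * L[k];
      const int ks = std::max(sire[k - 1], dam[k - 1]);
      const int kd = std::min(sire[k - 1], dam[k - 1]);
      if (ks > 0) {
        while (point[k] > ks) k = point[k];
        L[ks] += r;
        if (ks != point[k]) { point[ks] = point[k]; point[k] = ks; }
        if (kd > 0) {
          while (point[k] > kd) k = point[k];
          L[kd] += r;
          if (kd != point[k]) { point[kd] = point[k]; point[k] = kd; }
        }
      }
      fi += L[j] * L[j] * D[j];
      L[j] = 0.0;
      k = j;
      j = point[j];
      point[k] = 0;
    }
    F[i] = fi;
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = F[i + 1];
  return out;
}

// Recursive tabular numerator relationship matrix (dense; test scale).
// a_ij = 0.5 (a_j,s(i) + a_j,d(i)) for j < i; a_ii = 1 + 0.5 a_s(i),d(i).
// [[Rcpp::export(name = ".tabular_a")]]
NumericMatrix tabular_a(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1, d = dam[i] - 1;
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(j, s);
      if (d >= 0) v += 0.5 * A(j, d);
      A(j, i) = v;
      A(i, j) = v;
    }
    A(i, i) = 1.0 + ((s >= 0 && d >= 0) ? 0.5 * A(s, d) : 0.0);
  }
  return A;
}
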