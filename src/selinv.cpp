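#include <Rcpp.h>
using namespace Rcpp;

// Traces of inverse-coefficient-matrix blocks needed by EM-REML:
//   trKC  = sum_{(i,j) in Kinv} Kinv_ij * (C^-1)[nx+i, nx+j]
//   trCpp = sum_j (C^-1)[nx+nu+j, nx+nu+j]
// computed column-by-column through the sparse Cholesky factor
// (P C P' = L L'), far cheaper than materializing C^-1. The factor L is
// passed in CSC form; perm is 0-based with (P C P')_{ij} = C_{perm_i, perm_j}.
// Kinv triplets are 0-based in the u-block.
// [[Rcpp::export(name = ".mme_traces")]]
List mme_traces(IntegerVector Lp, IntegerVector Li, NumericVector Lx,
                IntegerVector perm, int nx, int nu, int np,
                IntegerVector ki, IntegerVector kj, NumericVector kx) {
  const int n = perm.size();
  std::vector<int> pos(n);
  for (int i = 0; i < n; ++i) pos[perm[i]] = i;

  // bucket Kinv entries by column
  std::vector<std::vector<int>> byCol(nu);
  for (int t = 0; t < ki.size(); ++t) byCol[kj[t]].push_back(t);

  std::vector<double> w(n);
  double trKC = 0.0, trCpp = 0.0;

  auto solveColumn = [&](int origCol) {
    // w := C^-1 e_origCol in original ordering
    std::fill(w.begin(), w.end(), 0.0);
    const int p0 = pos[origCol];
    w[p0] = 1.0;
    // forward solve L y = e (can start at p0: earlier entries stay zero)
    for (int k = p0; k < n; ++k) {
      if (w[k] == 0.0) continue;
      const double yk = w[k] / Lx[Lp[k]];  // diagonal first in each column
      w[k] = yk;
      for (int q = Lp[k] + 1; q < Lp[k + 1]; ++q) w[Li[q]] -= Lx[q] * yk;
    }
    // back solve L' z = y
    for (int k = n - 1; k >= 0; --k) {
      double s = w[k];
      for (int q = Lp[k] + 1; q < Lp[k + 1]; ++q) s -= Lx[q] * w[Li[q]];
      w[k] = s / Lx[Lp[k]];
    }
  };

  for (int j = 0; j < nu; ++j) {
    if (byCol[j].empty()) continue;
    solveColumn(nx + j);
    for (int t : byCol[j]) trKC += kx[t] * w[pos[nx + ki[t]]];
  }
  for (int j = 0; j < np; ++j) {
    const int c = nx + nu + j;
    solveColumn(c);
    trCpp += w[pos[c]];
  }
  return List::create(Named("trKC") = trKC, Named("trCpp") = trCpp);
}
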