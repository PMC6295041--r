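#include <Rcpp.h>
using namespace Rcpp;

// Gene-drop through a sorted pedigree with Haldane (no-interference)
// recombination: crossovers per chromosome ~ Poisson(length in Morgan),
// positions uniform along the chromosome.
//
// founderHaps: (2 * nFounders) x nSnp 0/1 matrix, rows 2k-1, 2k belong to
//   the k-th founder in pedigree order (animals with both parents unknown).
// posM: SNP position in Morgan within its chromosome; chr: 1-based
//   chromosome index per SNP (SNPs sorted by chromosome then position);
// chrLen: chromosome lengths in Morgan.
// founderFreq: allele frequencies used to draw a fresh haplotype when a
//   single parent is unknown.
//
// Returns (2n) x nSnp haplotype matrix; dosage = row 2i-1 + row 2i.
// [[Rcpp::export(name = ".gene_drop")]]
IntegerMatrix gene_drop(IntegerVector sire, IntegerVector dam,
                        IntegerMatrix founderHaps,
                        NumericVector posM, IntegerVector chr,
                        NumericVector chrLen, NumericVector founderFreq) {
  const int n = sire.size();
  const int m = posM.size();
  const int nChr = chrLen.size();
  if (founderHaps.ncol() != m) stop("founder haplotypes do not match map");

  // first/last SNP index per chromosome (SNPs sorted by chr)
  std::vector<int> chrStart(nChr, -1), chrEnd(nChr, -1);
  for (int j = 0; j < m; ++j) {
    const int c = chr[j] - 1;
    if (c < 0 || c >= nChr) stop("chromosome index out of range");
    if (chrStart[c] < 0) chrStart[c] = j;
    chrEnd[c] = j;
  }

  IntegerMatrix haps(2 * n, m);
  std::vector<int> gamete(m);

  // draw one gamete from parent p (0-based animal index) into 'gamete'
  auto meiosis = [&](int p) {
    for (int c = 0; c < nChr; ++c) {
      if (chrStart[c] < 0) continue;
      const double L = chrLen[c];
      const int ncx = (L > 0.0) ? (int) R::rpois(L) : 0;
      std::vector<double> cx(ncx);
      for (int t = 0; t < ncx; ++t) cx[t] = R::unif_rand() * L;
      std::sort(cx.begin(), cx.end());
      int cur = (R::unif_rand() < 0.5) ? 0 : 1;
      int t = 0;
      for (int j = chrStart[c]; j <= chrEnd[c]; ++j) {
        while (t < ncx && posM[j] > cx[t]) { cur ^= 1; ++t; }
        gamete[j] = haps(2 * p + cur, j);
      }
    }
  };

  int founderRow = 0;
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    if (s == 0 && d == 0) {
      if (founderRow + 1 >= founderHaps.nrow())
        stop("not enough founder haplotypes for the pedigree");
      for (int j = 0; j < m; ++j) {
        haps(2 * i, j) = founderHaps(founderRow, j);
        haps(2 * i + 1, j) = founderHaps(founderRow + 1, j);
      }
      founderRow += 2;
      continue;
    }
    // maternal/paternal gametes
    for (int which = 0; which < 2; ++which) {
      const int p = (which == 0) ? s : d;
      if (p > 0) {
        meiosis(p - 1);
        for (int j = 0; j < m; ++j) haps(2 * i + which, j) = gamete[j];
      } else {
        for (int j = 0; j < m; ++j)
          haps(2 * i + which, j) = (R::unif_rand() < founderFreq[j]) ? 1 : 0;
      }
    }
  }
  return haps;
}
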