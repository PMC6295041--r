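## Shared fixture builders for the test suite. All randomness is seeded by
## the caller; nothing here touches the global seed on load.

## a random valid pedigree: founders first, every later animal draws
## parents (possibly unknown) among earlier animals
randomPedigree <- function(n, founderShare = 0.2) {
  nf <- max(2L, round(founderShare * n))
  sire <- dam <- integer(n)
  for (i in (nf + 1):n) {
    sire[i] <- sample(0:(i - 1), 1)
    dam[i] <- sample(0:(i - 1), 1)
  }
  Pedigree(seq_len(n), sire, dam)
}

## small gene-drop dataset used across module tests
smallSim <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(nChrom = 4, nSnps = 200, nQtl = 60, nFounders = 60,
         familiesPerYear = 20, offspringPerFamily = 12, nYears = 1,
         genotypedFraction = 0.4, founderGens = 15),
    list(...))
  args$nQtl <- min(args$nQtl, args$nSnps %/% 2)
  simulateDataset(do.call(simParams, args), seed = seed)
}

## dosage matrix under Hardy-Weinberg proportions at given frequencies
hweDosages <- function(n, p, animals = paste0("a", seq_len(n))) {
  m <- length(p)
  d <- matrix(stats::rbinom(n * m, 2, rep(p, each = n)), nrow = n)
  rownames(d) <- animals
  d
}

## evenly spaced one-chromosome map
toyMap <- function(m, chrom = "chr1", spacingBp = 1e6) {
  data.frame(snp = paste0("s", seq_len(m)), chrom = chrom,
             pos = spacingBp * seq_len(m))
}
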