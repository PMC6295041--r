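#' Composite LD between adjacent SNPs
#'
#' For every within-chromosome pair of adjacent SNPs, the composite
#' (Burrows) disequilibrium is estimated from unphased dosages as
#' `D = cov(g_A, g_B) / 2`, and `r^2 = D^2 / [(var(g_A)/2)(var(g_B)/2)]` —
#' the squared dosage correlation, which equals the haplotype-based
#' `D^2 / (P_A P_a P_B P_b)` under Hardy-Weinberg proportions and requires
#' no phase. Distances are converted from bp to Morgan with a fixed
#' cM-per-Mb rate.
#'
#' @param geno a [GenotypeData-class] (post-QC; monomorphic SNPs are a QC
#'   violation and fatal).
#' @param cmPerMb map scale (default 1 cM/Mb).
#' @return data.frame: `chrom`, `snp1`, `snp2`, `distM`, `r2`.
#' @export
adjacentR2 <- function(geno, cmPerMb = 1) {
  pairwiseR2(geno, cmPerMb = cmPerMb, adjacentOnly = TRUE)
}

#' Composite LD between SNP pairs within chromosomes
#'
#' As [adjacentR2()], but over all within-chromosome pairs up to
#' `maxDistMb` apart (for decay curves); `adjacentOnly = TRUE` restricts to
#' adjacent pairs (for the per-chromosome mean LD).
#'
#' @param geno a [GenotypeData-class].
#' @param maxDistMb maximum pair distance in Mb (ignored for adjacent
#'   pairs).
#' @param cmPerMb map scale.
#' @param adjacentOnly adjacent pairs only?
#' @return data.frame: `chrom`, `snp1`, `snp2`, `distM`, `r2`.
#' @export
pairwiseR2 <- function(geno, maxDistMb = 10, cmPerMb = 1,
                       adjacentOnly = FALSE) {
  X <- geno@dosage
  if (anyNA(X)) stop("missing dosages: run snpQc() first")
  vars <- apply(X, 2, stats::var)
  if (any(vars == 0))
    stop("monomorphic SNP encountered (QC violation): ",
         colnames(X)[vars == 0][1])
  chrom <- as.character(GenomicRanges::seqnames(geno@map))
  pos <- GenomicRanges::start(geno@map)
  out <- list()
  for (cx in split(seq_len(ncol(X)), factor(chrom, unique(chrom)))) {
    if (length(cx) < 2) next
    if (adjacentOnly) {
      i <- cx[-length(cx)]
      j <- cx[-1]
    } else {
      pr <- utils::combn(cx, 2)
      keep <- (pos[pr[2, ]] - pos[pr[1, ]]) <= maxDistMb * 1e6
      i <- pr[1, keep]
      j <- pr[2, keep]
    }
    if (length(i) == 0) next
    r2 <- vapply(seq_along(i), function(k)
      stats::cor(X[, i[k]], X[, j[k]])^2, numeric(1))
    out[[length(out) + 1]] <- data.frame(
      chrom = chrom[i], snp1 = colnames(X)[i], snp2 = colnames(X)[j],
      distM = (pos[j] - pos[i]) * cmPerMb / 1e8, r2 = r2)
  }
  if (length(out) == 0) stop("no SNP pairs available")
  do.call(rbind, out)
}

#' Mean LD per chromosome and genome-wide
#'
#' @param records output of [adjacentR2()] / [pairwiseR2()].
#' @return list with `byChrom` (data.frame `chrom`, `meanR2`, `meanDistM`,
#'   `nPairs`) and `genome` (overall mean r2).
#' @export
meanR2 <- function(records) {
  sp <- split(records, factor(records$chrom, unique(records$chrom)))
  byChrom <- data.frame(
    chrom = names(sp),
    meanR2 = vapply(sp, function(d) mean(d$r2), numeric(1)),
    meanDistM = vapply(sp, function(d) mean(d$distM), numeric(1)),
    nPairs = vapply(sp, nrow, integer(1)))
  rownames(byChrom) <- NULL
  list(byChrom = byChrom, genome = mean(records$r2))
}

#' Fit the Sved LD-decay curve per chromosome
#'
#' Nonlinear least squares of `r^2` on `1 / (1 + 4 Ne d)` with `d` in
#' Morgan; returns one effective-population-size estimate per chromosome.
#' Non-converging chromosomes are flagged and fall back to the mean-r2
#' estimator ([neFromMeanR2()]).
#'
#' @param records LD records (`distM`, `r2`, `chrom`).
#' @param sampleN number of genotyped animals (for the fallback's sample
#'   correction); `Inf` disables it.
#' @return data.frame: `chrom`, `Ne`, `converged`, `nPairs`, `sse`.
#' @export
fitSvedDecay <- function(records, sampleN = Inf) {
  sp <- split(records, factor(records$chrom, unique(records$chrom)))
  rows <- lapply(names(sp), function(cn) {
    d <- sp[[cn]]
    if (nrow(d) < 10)
      warning("chromosome ", cn, " has fewer than 10 pairs")
    start <- list(Ne = max(1e-3, (1 / max(mean(d$r2), 1e-6) - 1) /
                             (4 * max(mean(d$distM), 1e-9))))
    fit <- tryCatch(
      minpack.lm::nlsLM(r2 ~ 1 / (1 + 4 * Ne * distM), data = d,
                        start = start, lower = 1e-6,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      ne <- neFromMeanR2(mean(d$r2), mean(d$distM), N = sampleN)
      data.frame(chrom = cn, Ne = ne, converged = FALSE,
                 nPairs = nrow(d), sse = NA_real_)
    } else {
      data.frame(chrom = cn, Ne = unname(stats::coef(fit)["Ne"]),
                 converged = TRUE, nPairs = nrow(d),
                 sse = sum(stats::resid(fit)^2))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Effective population size from mean LD
#'
#' `Ne_t = (4 d_t)^-1 [ (r2_t - 1/N)^-1 - alpha ]` with `d_t` the mean
#' distance (Morgan) of the pairs behind `r2_t`, `N` the number of
#' genotyped animals (sampling correction) and `alpha = 2` when mutation is
#' accounted for (1 otherwise).
#'
#' @param r2Mean mean r2 (vectorized over chromosomes).
#' @param dt mean pair distance in Morgan (recycled).
#' @param N genotyped sample size (`Inf` for no correction).
#' @param alpha mutation adjustment, 1 or 2 (default 2).
#' @return Ne estimate(s); `NA` (flagged by a warning) where
#'   `r2Mean <= 1/N`.
#' @export
neFromMeanR2 <- function(r2Mean, dt, N = Inf, alpha = 2) {
  adj <- r2Mean - 1 / N
  bad <- adj <= 0
  if (any(bad)) warning("mean r2 not above the 1/N sampling floor; Ne undefined")
  ne <- (1 / adj - alpha) / (4 * dt)
  ne[bad] <- NA_real_
  ne
}

#' Genome-wide effective population size from adjacent-SNP LD
#'
#' Per chromosome, mean adjacent-pair r2 and the mean distance of those
#' pairs feed [neFromMeanR2()]; the genome-wide value is the unweighted
#' mean over chromosomes (or length-weighted with
#' `lengthWeighted = TRUE`).
#'
#' @param geno a [GenotypeData-class].
#' @param alpha mutation adjustment (default 2).
#' @param cmPerMb map scale.
#' @param lengthWeighted weight chromosomes by map length?
#' @return list: `byChrom` data.frame (`chrom`, `meanR2`, `Ne`), `Ne`
#'   (genome-wide).
#' @export
neFromLd <- function(geno, alpha = 2, cmPerMb = 1, lengthWeighted = FALSE) {
  rec <- adjacentR2(geno, cmPerMb = cmPerMb)
  m <- meanR2(rec)$byChrom
  N <- length(geno@animals)
  m$Ne <- neFromMeanR2(m$meanR2, m$meanDistM, N = N, alpha = alpha)
  w <- if (lengthWeighted) {
    len <- vapply(split(rec$distM, factor(rec$chrom, unique(rec$chrom))),
                  sum, numeric(1))
    len / sum(len)
  } else rep(1 / nrow(m), nrow(m))
  list(byChrom = m, Ne = sum(w * m$Ne, na.rm = TRUE) /
         sum(w[!is.na(m$Ne)]))
}
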