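#' Back-solve SNP effects from genomic breeding values
#'
#' Standard weighted-ssGBLUP back-solving:
#' `a = D M' G^-1 u / (2 sum p_j (1 - p_j))`, with `M` the centered dosage
#' matrix and `G` built from the same `M`, `p` and `D`. With an unblended,
#' invertible `G` and unit weights, `M a` reconstructs `u` exactly; in
#' production the blended `G` is used for numerical stability.
#'
#' @param uGeno breeding values of the genotyped animals (order of
#'   `geno@animals`).
#' @param geno a [GenotypeData-class] (post-QC).
#' @param p allele frequencies.
#' @param weights per-SNP weights `D` (default 1).
#' @param G the genomic relationship used in the fit (rebuilt unblended
#'   from `geno` when missing).
#' @param pseudoInverse use the Moore-Penrose inverse of `G` instead of
#'   failing on singularity (e.g. when `p` equals the sample frequencies,
#'   which centers `M` exactly and puts the unit vector in the null space
#'   of `G`).
#' @return per-SNP additive effects on the dosage scale, named by SNP.
#' @export
backsolveSnpEffects <- function(uGeno, geno, p = alleleFrequencies(geno),
                                weights = NULL, G = NULL,
                                pseudoInverse = FALSE) {
  M <- sweep(geno@dosage, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  if (is.null(G)) G <- buildG(geno, p, weights = weights)
  Gu <- if (pseudoInverse) {
    eg <- eigen(G, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-10
    eg$vectors[, pos, drop = FALSE] %*%
      ((crossprod(eg$vectors[, pos, drop = FALSE], uGeno)) / eg$values[pos])
  } else {
    tryCatch(solve(G, uGeno),
             error = function(e)
               stop("G is singular; blend before back-solving",
                    call. = FALSE))
  }
  a <- as.numeric(crossprod(M, Gu)) / denom
  if (!is.null(weights)) a <- a * weights
  names(a) <- colnames(geno@dosage)
  a
}

#' Nonlinear-A SNP weights
#'
#' `d_j = CT^min(|a_j| / sd(a) - 2, cap)`: departures from normality are
#' rewarded, and the exponent cap (5 by default) bounds the maximum weight
#' at `CT^5`, which gives the scheme its convergence behaviour under
#' polygenic architectures.
#'
#' @param a estimated SNP effects.
#' @param ct departure-from-normality constant (default 1.125).
#' @param cap maximum exponent (default 5).
#' @return per-SNP weights `d > 0`; all 1 (with a warning) when the effects
#'   are all zero.
#' @export
nonlinearAWeights <- function(a, ct = 1.125, cap = 5) {
  sda <- stats::sd(a)
  if (is.na(sda) || sda == 0) {
    warning("all SNP effects zero; weights set to 1")
    return(rep(1, length(a)))
  }
  ct^pmin(abs(a) / sda - 2, cap)
}

#' Iterative weighted ssGBLUP
#'
#' Iteration 1 fits ssGBLUP with homogeneous SNP weights (`D = I`); each
#' subsequent iteration rebuilds `G` with the current weights, refits,
#' back-solves SNP effects and recomputes nonlinear-A weights. Per
#' iteration, predictive ability and the inflation slope are recorded on a
#' held-out subset of genotyped phenotyped animals (for iteration
#' selection) while SNP effects come from the full-data fit.
#'
#' @param ped,geno,pheno dataset pieces.
#' @param spec the trait's [ModelSpec-class].
#' @param vc variance components for the fits.
#' @param nIter number of weight iterations (default 5).
#' @param blend `A22` blending proportion.
#' @param ct,cap nonlinear-A parameters.
#' @param holdout fraction of genotyped phenotyped animals held out for the
#'   per-iteration diagnostics.
#' @param seed seed for the held-out split.
#' @param weightScheme `"nonlinearA"` (production) or the experimental
#'   `"linear"` scheme `d_j = a_j^2 2 p_j (1 - p_j)` (normalized to mean
#'   1), which lacks a weight cap and is known to diverge under polygenic
#'   architectures — kept only to reproduce that behaviour.
#' @return list with `iterations` (per-iteration list: `effects`,
#'   `weights`, `r`, `b1`, `maxWeightChange`, `fit`) and `selected`, the
#'   iteration index with the highest held-out predictive ability (ties
#'   broken by least inflation, `|b1 - 1|`).
#' @export
wssgblup <- function(ped, geno, pheno, spec, vc, nIter = 5, blend = 0.05,
                     ct = 1.125, cap = 5, holdout = 0.2, seed = 1,
                     weightScheme = c("nonlinearA", "linear")) {
  weightScheme <- match.arg(weightScheme)
  if (length(geno@animals) == 0) stop("no genotyped animals")
  trait <- spec@trait
  p <- alleleFrequencies(geno)
  genoIdx <- pedigreeIds(ped, geno@animals)
  A22 <- extractA22(ped, genoIdx)
  Ainv <- buildAInverse(ped)
  fullDesign <- buildDesign(pheno, spec, ped)

  elig <- intersect(geno@animals, pheno$animal[!is.na(pheno[[trait]])])
  set.seed(deriveSeed(seed, "wssgblup_holdout"))
  val <- sample(elig, max(3, round(holdout * length(elig))))
  masked <- maskPhenotypes(pheno, trait, val)
  maskedDesign <- buildDesign(masked, spec, ped)

  d <- rep(1, length(p))
  iterations <- vector("list", nIter)
  prevD <- d
  for (it in seq_len(nIter)) {
    G <- buildG(geno, p, weights = d)
    Gb <- blendG(G, A22, beta = blend)
    Hinv <- buildHInverse(Ainv, A22, Gb, genoIdx)
    fit <- solveMME(fullDesign, Hinv, vc, method = "ssGBLUP")
    ystar <- adjustedPhenotypes(fullDesign, fixedEffects(fit))
    if (!is.null(fullDesign$W))
      ystar <- ystar - as.numeric(fullDesign$W %*% commonEnv(fit))

    trainFit <- solveMME(maskedDesign, Hinv, vc, method = "ssGBLUP")
    recAnimal <- ped@labels[fullDesign$animals]
    idx <- match(val, recAnimal)
    uv <- ebv(trainFit)[pedigreeIds(ped, val)]
    r <- predictiveAbility(uv, ystar[idx])
    b1 <- unname(inflationRegression(ystar[idx], uv)["b1"])

    a <- backsolveSnpEffects(ebv(fit)[genoIdx], geno, p, weights = d, G = Gb)
    dNew <- if (weightScheme == "nonlinearA") {
      nonlinearAWeights(a, ct = ct, cap = cap)
    } else {
      dl <- a^2 * 2 * p * (1 - p)
      if (mean(dl) > 0) dl / mean(dl) else rep(1, length(dl))
    }
    iterations[[it]] <- list(iteration = it, effects = a, weights = d,
                             r = r, b1 = b1,
                             maxWeightChange = max(abs(d - prevD)),
                             fit = fit)
    prevD <- d
    d <- dNew
  }
  rs <- vapply(iterations, `[[`, numeric(1), "r")
  b1s <- vapply(iterations, `[[`, numeric(1), "b1")
  ord <- order(-rs, abs(b1s - 1))
  list(iterations = iterations, selected = ord[1])
}

#' Variance explained by windows of adjacent SNPs
#'
#' Non-overlapping windows of `windowSize` adjacent SNPs within each
#' chromosome (a shorter trailing window is kept). The window variance is
#' the independent-locus sum `sum 2 p_j (1 - p_j) a_j^2`, expressed as a
#' percentage of the same sum over all SNPs, so the percentages total 100.
#'
#' @param a per-SNP effects (map order).
#' @param p allele frequencies (map order).
#' @param map `GRanges` SNP map.
#' @param windowSize SNPs per window (default 20).
#' @param sliding if `TRUE`, one overlapping window starts at every SNP
#'   (percentages then no longer total 100, since SNPs are counted in up
#'   to `windowSize` windows); default distinct windows.
#' @return data.frame: `window`, `chrom`, `startBp`, `endBp`, `midBp`,
#'   `nSnps`, `variance`, `pctVariance`.
#' @export
windowVariances <- function(a, p, map, windowSize = 20, sliding = FALSE) {
  stopifnot(length(a) == length(map), length(p) == length(map))
  chrom <- as.character(GenomicRanges::seqnames(map))
  pos <- GenomicRanges::start(map)
  v <- 2 * p * (1 - p) * a^2
  total <- sum(v)
  chromIdx <- split(seq_along(a), factor(chrom, unique(chrom)))
  rows <- list()
  for (ix in chromIdx) {
    starts <- if (sliding) seq_along(ix) else
      seq(1, length(ix), by = windowSize)
    for (s in starts) {
      w <- ix[s:min(s + windowSize - 1, length(ix))]
      rows[[length(rows) + 1]] <- data.frame(
        window = paste0(chrom[ix[1]], "_", s),
        chrom = chrom[ix[1]],
        startBp = pos[w[1]], endBp = pos[w[length(w)]],
        midBp = (pos[w[1]] + pos[w[length(w)]]) / 2,
        nSnps = length(w), variance = sum(v[w]))
    }
  }
  out <- do.call(rbind, rows)
  if (!sliding) {
    ## stable distinct-window labels: sequential index per chromosome
    out$window <- unlist(lapply(split(out$chrom, factor(out$chrom,
                                                        unique(out$chrom))),
                                function(cc) paste0(cc, "_",
                                                    seq_along(cc))),
                         use.names = FALSE)
  }
  out$pctVariance <- if (total > 0) 100 * out$variance / total else
    rep(0, nrow(out))
  rownames(out) <- NULL
  out
}

#' Plot-ready Manhattan table
#'
#' One row per window: chromosome, window midpoint (bp) and the percentage
#' of additive genetic variance explained.
#'
#' @param windows output of [windowVariances()].
#' @return data.frame `chrom`, `midBp`, `pctVariance`.
#' @export
manhattanTable <- function(windows) {
  windows[, c("chrom", "midBp", "pctVariance")]
}
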