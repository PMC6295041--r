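#' Construct a GenotypeData object
#'
#' @param dosage numeric matrix of allele dosages (animals x SNPs); rownames
#'   (or `animals`) give animal labels. Missing calls are `NA`.
#' @param map a `GRanges` (one width-1 range per SNP, names = SNP ids), or a
#'   data.frame with columns `chrom` and `pos` (bp).
#' @param animals optional animal labels (default rownames of `dosage`).
#' @return A [GenotypeData-class] object.
#' @export
GenotypeData <- function(dosage, map, animals = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(animals)) stop("animal labels required (rownames or animals=)")
  if (is.data.frame(map)) {
    snp <- if (!is.null(map$snp)) as.character(map$snp) else
      colnames(dosage) %||% paste0("snp", seq_len(nrow(map)))
    map <- GenomicRanges::GRanges(
      seqnames = as.character(map$chrom),
      ranges = IRanges::IRanges(start = as.numeric(map$pos), width = 1))
    names(map) <- snp
  }
  if (is.null(names(map)))
    names(map) <- colnames(dosage) %||% paste0("snp", seq_along(map))
  o <- order(as.integer(GenomicRanges::seqnames(map)),
             GenomicRanges::start(map))
  map <- map[o]
  dosage <- dosage[, o, drop = FALSE]
  colnames(dosage) <- names(map)
  rownames(dosage) <- animals
  new("GenotypeData", dosage = dosage, animals = as.character(animals),
      map = map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dosage matrix accessor
#' @param geno a [GenotypeData-class].
#' @export
dosages <- function(geno) geno@dosage

#' SNP map accessor
#' @param geno a [GenotypeData-class].
#' @return `GRanges` of SNP positions.
#' @export
snpMap <- function(geno) geno@map

#' Genotyped animal labels
#' @param geno a [GenotypeData-class].
#' @export
genotypedAnimals <- function(geno) geno@animals

#' SNP and animal quality control
#'
#' Animals are removed first if their call rate is below `animalCallMin`;
#' SNP statistics are then computed on the surviving animals, and SNPs are
#' removed if monomorphic, if their call rate is below `snpCallMin`, or if
#' their minor allele frequency is strictly lower than `mafMin` (a SNP at
#' exactly the threshold is retained). Remaining missing calls are imputed
#' to the SNP mean dosage (`2p`).
#'
#' @param geno a [GenotypeData-class], possibly with missing calls.
#' @param mafMin minimum minor allele frequency (default 0.05).
#' @param snpCallMin minimum SNP call rate (default 0.90).
#' @param animalCallMin minimum per-animal call rate (default 0.90).
#' @return list with `geno` (filtered, imputed), and `report` (data.frame
#'   `filter`, `n_removed`).
#' @export
snpQc <- function(geno, mafMin = 0.05, snpCallMin = 0.90,
                  animalCallMin = 0.90) {
  X <- geno@dosage
  animCall <- rowMeans(!is.na(X))
  dropAnim <- animCall < animalCallMin
  X <- X[!dropAnim, , drop = FALSE]

  snpCall <- colMeans(!is.na(X))
  p <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  mono <- apply(X, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0 || all(v == v[1])
  })
  dropCall <- snpCall < snpCallMin
  dropMono <- mono & !dropCall
  dropMaf <- (maf < mafMin) & !mono & !dropCall
  dropSnp <- dropCall | dropMono | dropMaf

  report <- data.frame(
    filter = c("animal_call_rate", "snp_call_rate", "monomorphic", "maf"),
    n_removed = c(sum(dropAnim), sum(dropCall), sum(dropMono), sum(dropMaf)))
  if (all(dropSnp)) {
    print(report)
    stop("all SNPs removed by quality control")
  }
  X <- X[, !dropSnp, drop = FALSE]
  ## mean-impute remaining missing to 2p (column mean)
  if (anyNA(X)) {
    cm <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- cm[idx[, 2]]
  }
  out <- new("GenotypeData", dosage = X,
             animals = geno@animals[!dropAnim],
             map = geno@map[!dropSnp])
  list(geno = out, report = report)
}

#' Current allele frequencies
#'
#' `p_j` = mean dosage at SNP `j` over non-missing calls, divided by 2;
#' computed from the current genotyped sample.
#'
#' @param geno a [GenotypeData-class].
#' @return numeric vector of allele frequencies, named by SNP.
#' @export
alleleFrequencies <- function(geno) {
  colMeans(geno@dosage, na.rm = TRUE) / 2
}

#' VanRaden genomic relationship matrix
#'
#' `G = M D M' / (2 sum p_j (1 - p_j))` with `M` the dosage matrix centered
#' by twice the current allele frequencies and `D` a diagonal matrix of
#' per-SNP weights (identity by default: all SNPs weighted homogeneously).
#'
#' @param geno a [GenotypeData-class] (post-QC: no missing, no monomorphic
#'   SNPs).
#' @param p allele frequencies (computed from `geno` if missing).
#' @param weights per-SNP weights `D` (default all 1).
#' @return dense symmetric matrix with genotyped animal labels as dimnames.
#' @export
buildG <- function(geno, p = alleleFrequencies(geno), weights = NULL) {
  X <- geno@dosage
  if (anyNA(X)) stop("missing dosages: run snpQc() first")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("zero denominator: all SNPs monomorphic?")
  M <- sweep(X, 2, 2 * p)
  if (is.null(weights)) {
    G <- tcrossprod(M) / denom
  } else {
    if (length(weights) != ncol(M)) stop("one weight per SNP required")
    G <- tcrossprod(sweep(M, 2, weights, "*"), M) / denom
  }
  dimnames(G) <- list(geno@animals, geno@animals)
  (G + t(G)) / 2
}

#' Blend G with the pedigree relationship block
#'
#' `(1 - beta) G + beta A22`; the default 5% blending guards against a
#' singular genomic matrix.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationship matrix over the same animals.
#' @param beta blending proportion in `[0, 1)`.
#' @export
blendG <- function(G, A22, beta = 0.05) {
  if (!is.numeric(beta) || length(beta) != 1 || beta < 0 || beta >= 1)
    stop("beta must be a single value in [0, 1)")
  if (!all(dim(G) == dim(A22))) stop("G and A22 are not conformable")
  (1 - beta) * G + beta * A22
}

#' Assemble the single-step H-inverse
#'
#' `H^-1 = A^-1 + [0 0; 0 G_b^-1 - A22^-1]` with the genomic block added
#' over the genotyped animals. Returns a sparse symmetric matrix (the
#' genotyped block is dense inside it).
#'
#' @param Ainv sparse pedigree relationship inverse (full pedigree).
#' @param A22 dense pedigree relationship matrix of the genotyped animals.
#' @param Gb blended genomic relationship matrix (must be invertible).
#' @param genoIdx internal pedigree ids of the genotyped animals, in the
#'   row order of `Gb`/`A22`. Empty set returns `Ainv` unchanged.
#' @return sparse symmetric matrix of the same dimension as `Ainv`.
#' @export
buildHInverse <- function(Ainv, A22, Gb, genoIdx) {
  genoIdx <- as.integer(genoIdx)
  if (length(genoIdx) == 0) return(Ainv)
  Ginv <- tryCatch(chol2inv(chol(Gb)),
                   error = function(e)
                     stop("blended G is singular; increase the blending ",
                          "proportion (blendG beta)", call. = FALSE))
  A22inv <- chol2inv(chol(A22))
  delta <- Ginv - A22inv
  ng <- length(genoIdx)
  D <- Matrix::sparseMatrix(
    i = rep(genoIdx, times = ng),
    j = rep(genoIdx, each = ng),
    x = as.vector(delta),
    dims = dim(Ainv))
  Matrix::forceSymmetric(Ainv + D)
}
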