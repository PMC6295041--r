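#' Read a dosage text matrix with a sidecar SNP map
#'
#' The dosage file is tab/whitespace-delimited with a header of SNP ids and
#' a first column of animal labels; missing calls are `NA` or `-9`. The map
#' file is a CSV with columns `snp` (optional), `chrom`, `pos`.
#'
#' @param dosagePath dosage matrix file.
#' @param mapPath SNP map CSV.
#' @return a [GenotypeData-class].
#' @export
readGenotypes <- function(dosagePath, mapPath) {
  g <- utils::read.table(dosagePath, header = TRUE, check.names = FALSE,
                         na.strings = c("NA", "-9"))
  dos <- as.matrix(g[, -1, drop = FALSE])
  rownames(dos) <- as.character(g[[1]])
  map <- utils::read.csv(mapPath, stringsAsFactors = FALSE)
  if (is.null(map$snp)) map$snp <- colnames(dos)
  o <- match(colnames(dos), map$snp)
  if (anyNA(o)) stop("SNP missing from map: ", colnames(dos)[is.na(o)][1])
  GenotypeData(dos, map[o, , drop = FALSE], animals = rownames(dos))
}

#' Read PLINK .raw additive dosages with a .map file
#'
#' Supports the PLINK `--recode A` dialect: header
#' `FID IID PAT MAT SEX PHENOTYPE snp1_A ...`, additive dosage columns,
#' `NA` for missing; the `.map` file provides chromosome and bp position
#' (columns: chrom, snp, cM, pos).
#'
#' @param rawPath `.raw` file.
#' @param mapPath `.map` file.
#' @return a [GenotypeData-class].
#' @export
readPlinkRaw <- function(rawPath, mapPath) {
  g <- utils::read.table(rawPath, header = TRUE, check.names = FALSE,
                         na.strings = c("NA", "-9"))
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(fixed %in% names(g)))
    stop(".raw file lacks the PLINK fixed columns")
  dos <- as.matrix(g[, setdiff(names(g), fixed), drop = FALSE])
  rownames(dos) <- as.character(g$IID)
  ## strip the _allele suffix PLINK appends to SNP ids
  colnames(dos) <- sub("_[ACGT0-9]+$", "", colnames(dos))
  map <- utils::read.table(mapPath, header = FALSE,
                           col.names = c("chrom", "snp", "cm", "pos"))
  o <- match(colnames(dos), map$snp)
  if (anyNA(o)) stop("SNP missing from .map: ", colnames(dos)[is.na(o)][1])
  GenotypeData(dos, map[o, c("snp", "chrom", "pos")],
               animals = rownames(dos))
}

#' Write a QC report
#' @param report the `report` element of [snpQc()].
#' @param path CSV path.
#' @export
writeQcReport <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write breeding-value solutions
#'
#' One row per animal: label, EBV, parent average, and a reliability
#' placeholder.
#'
#' @param fit a [MixedModelFit-class].
#' @param ped the [Pedigree-class] behind the fit.
#' @param path CSV path.
#' @export
writeSolutions <- function(fit, ped, path) {
  u <- ebv(fit)
  utils::write.csv(
    data.frame(animal = ped@labels, ebv = u,
               parent_average = parentAverage(u, ped),
               reliability = NA_real_),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
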