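#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom GenomicRanges GRanges
#' @useDynLib StepBLUP, .registration = TRUE
NULL

#' Pedigree of a breeding population
#'
#' An ordered trio pedigree with internal ids `1..n`, sorted so that parents
#' always precede their offspring. `0` denotes an unknown parent, treated as
#' an unrelated, non-inbred founder. The `labels` slot retains the original
#' identifiers so external tables can be mapped onto internal ids.
#'
#' @slot sire integer vector of sire internal ids (0 = unknown).
#' @slot dam integer vector of dam internal ids (0 = unknown).
#' @slot labels character vector of original animal identifiers.
#' @slot yearClass integer year-class (generation) label per animal; `NA`
#'   when not supplied (generation is then derived as maximal ancestral
#'   depth where needed).
#'
#' @export
setClass("Pedigree",
  representation(sire = "integer", dam = "integer",
                 labels = "character", yearClass = "integer"),
  validity = function(object) {
    n <- length(object@sire)
    if (length(object@dam) != n) return("sire/dam length mismatch")
    if (length(object@labels) != n) return("labels length mismatch")
    if (length(object@yearClass) != n) return("yearClass length mismatch")
    idx <- seq_len(n)
    if (any(object@sire < 0L) || any(object@dam < 0L))
      return("negative parent id")
    if (any(object@sire >= idx) || any(object@dam >= idx))
      return("parents must precede offspring (pedigree not sorted)")
    if (anyDuplicated(object@labels)) return("duplicated animal identifiers")
    TRUE
  })

#' Genotype dosages with a SNP map
#'
#' Allele dosages (0/1/2, possibly missing before QC) for a set of animals,
#' together with the genomic position of each SNP held as a
#' [GenomicRanges::GRanges] (one width-1 range per SNP, sorted by chromosome
#' and position).
#'
#' @slot dosage numeric matrix, animals x SNPs; rownames are animal labels.
#' @slot animals character vector of animal labels (pedigree labels).
#' @slot map `GRanges` with one range per SNP; names are SNP ids.
#'
#' @export
setClass("GenotypeData",
  representation(dosage = "matrix", animals = "character", map = "GRanges"),
  validity = function(object) {
    if (nrow(object@dosage) != length(object@animals))
      return("dosage rows do not match animals")
    if (ncol(object@dosage) != length(object@map))
      return("dosage columns do not match SNP map")
    ok <- is.na(object@dosage) | (object@dosage >= 0 & object@dosage <= 2)
    if (!all(ok)) return("dosages must be in [0, 2] or NA")
    chr <- as.integer(GenomicRanges::seqnames(object@map))
    pos <- GenomicRanges::start(object@map)
    if (length(chr) > 1 && any(diff(chr) < 0 | (diff(chr) == 0 & diff(pos) <= 0)))
      return("SNP map must be sorted with strictly increasing positions within chromosome")
    TRUE
  })

#' Model specification for a single-trait animal model
#'
#' Wires a phenotype column to the fixed-effect structure of the evaluation
#' model: `y = Xb + Zu + Wp + e`, with `u` the additive genetic effect
#' (relationship matrix A or H) and `p` an independent common-environment
#' effect shared by full sibs from the same spawn.
#'
#' @slot trait name of the phenotype column.
#' @slot fixed one-sided formula for the fixed effects (factors and nested
#'   covariates), evaluated against the phenotype table.
#' @slot spawn name of the common-environment (full-sib spawn) column, or
#'   `NA_character_` to omit the effect.
#'
#' @export
setClass("ModelSpec",
  representation(trait = "character", fixed = "formula", spawn = "character"))

#' Solutions of the mixed-model equations
#'
#' @slot b named fixed-effect estimates.
#' @slot u breeding values for every pedigree animal (phenotyped or not).
#' @slot pe named common-environment effects (length 0 when the model has
#'   none).
#' @slot vc list with `sigma2_u`, `sigma2_p`, `sigma2_e` used in the solve.
#' @slot method `"BLUP"` or `"ssGBLUP"` (which relationship inverse was
#'   supplied).
#' @slot diagnostics list: solver used, relative residual norm, iterations.
#'
#' @export
setClass("MixedModelFit",
  representation(b = "numeric", u = "numeric", pe = "numeric", vc = "list",
                 method = "character", diagnostics = "list"))

#' A simulated breeding-program dataset with known truth
#'
#' @slot ped [Pedigree-class] of the simulated population.
#' @slot geno [GenotypeData-class] for the genotyped subset (post gene-drop).
#' @slot pheno data.frame of phenotype records (offspring only).
#' @slot truth list: true breeding values per trait, QTL indices and effects,
#'   realized and target variance components.
#' @slot params the [simParams()] list used.
#'
#' @export
setClass("SimulatedDataset",
  representation(ped = "Pedigree", geno = "GenotypeData",
                 pheno = "data.frame", truth = "list", params = "list"))

setMethod("show", "Pedigree", function(object) {
  n <- length(object@sire)
  nf <- sum(object@sire == 0L & object@dam == 0L)
  cat("Pedigree with", n, "animals (", nf, "founders )\n")
  if (!all(is.na(object@yearClass)))
    cat("  year-classes:", paste(sort(unique(object@yearClass)), collapse = ", "), "\n")
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@dosage), "animals x",
      ncol(object@dosage), "SNPs on",
      length(unique(as.character(GenomicRanges::seqnames(object@map)))), "chromosomes\n")
  nm <- sum(is.na(object@dosage))
  if (nm > 0) cat("  missing calls:", nm, "\n")
})

setMethod("show", "MixedModelFit", function(object) {
  cat("MixedModelFit (", object@method, "): ",
      length(object@b), " fixed effects, ",
      length(object@u), " breeding values, ",
      length(object@pe), " common-environment effects\n", sep = "")
  cat("  solver:", object@diagnostics$solver,
      " rel. residual:", format(object@diagnostics$relResidual, digits = 3), "\n")
})

setMethod("show", "SimulatedDataset", function(object) {
  cat("SimulatedDataset:", length(object@ped@sire), "animals,",
      nrow(object@pheno), "phenotype records,",
      nrow(object@geno@dosage), "genotyped at",
      ncol(object@geno@dosage), "SNPs\n")
})
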