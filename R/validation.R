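#' Derive a reproducible sub-seed
#'
#' All randomized steps draw their seed from a single master seed through
#' this scheme, so every table is reproducible from one integer.
#'
#' @param master master seed (integer).
#' @param stage character stage name (hashed by UTF-8 code sum).
#' @param index replicate/fold counter.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(master, stage, index = 0L) {
  h <- sum(utf8ToInt(stage)) %% 104729
  as.integer((as.numeric(master) * 48271 + h * 7919 + index * 104729) %%
               2147483646 + 1)
}

#' Random k-fold partitions
#'
#' Per replicate, a random partition of `ids` into `k` near-equal,
#' mutually exclusive and exhaustive folds; each fold serves once as the
#' validation group.
#'
#' @param ids vector of animal labels (genotyped animals with phenotypes).
#' @param k number of folds (5 or 10 in the study design; `k = length(ids)`
#'   gives leave-one-out).
#' @param replicates number of replicate partitions.
#' @param seed master seed.
#' @return list of replicates, each a list of `k` label vectors.
#' @export
kfoldSplit <- function(ids, k = 5, replicates = 5, seed = 1) {
  n <- length(ids)
  if (k > n) stop("k = ", k, " exceeds the number of animals (", n, ")")
  lapply(seq_len(replicates), function(r) {
    set.seed(deriveSeed(seed, "kfold", r))
    perm <- sample(ids)
    fold <- sort(rep(seq_len(k), length.out = n))
    split(perm, fold)
  })
}

#' Split genotyped full-sib families into training and validation halves
#'
#' Within each family, members are randomly halved; with an odd family
#' size the extra member goes to training. Families of size 1 are assigned
#' to training.
#'
#' @param family factor/vector of family ids, named by animal label.
#' @param seed seed.
#' @param perFamily halve each family separately (default); `FALSE` draws
#'   one global random half of all the sibs instead.
#' @return list with `training` and `validation` label vectors.
#' @export
fullsibSplit <- function(family, seed = 1, perFamily = TRUE) {
  if (is.null(names(family))) stop("family vector must be named by animal")
  set.seed(deriveSeed(seed, "fullsib"))
  if (!perFamily) {
    ids <- names(family)
    v <- sample(ids, floor(length(ids) / 2))
    return(list(training = setdiff(ids, v), validation = v))
  }
  train <- character(0); valid <- character(0)
  for (fam in split(names(family), as.character(family))) {
    nf <- length(fam)
    if (nf == 1) { train <- c(train, fam); next }
    nv <- floor(nf / 2)
    v <- sample(fam, nv)
    valid <- c(valid, v)
    train <- c(train, setdiff(fam, v))
  }
  list(training = train, validation = valid)
}

#' Mask phenotypes of selected animals
#'
#' Sets the trait value to `NA` for the given animals, leaving all other
#' records (and the validation-set membership) untouched.
#'
#' @param pheno phenotype data.frame with an `animal` column.
#' @param trait trait column name.
#' @param animals labels whose phenotypes are removed.
#' @return the masked data.frame.
#' @export
maskPhenotypes <- function(pheno, trait, animals) {
  pheno[[trait]][pheno$animal %in% animals] <- NA
  pheno
}

#' Predictive ability
#'
#' Pearson correlation between breeding values of the validation animals
#' and their phenotypes adjusted for fixed effects (`y*` from the full-data
#' fit).
#'
#' @param u breeding values of validation animals.
#' @param ystar adjusted phenotypes of the same animals.
#' @return correlation, or `NA` (with a warning) when degenerate.
#' @export
predictiveAbility <- function(u, ystar) {
  if (length(u) < 3) {
    warning("fewer than 3 validation animals; predictive ability undefined")
    return(NA_real_)
  }
  if (stats::sd(u) == 0 || stats::sd(ystar) == 0) {
    warning("zero variance; predictive ability undefined")
    return(NA_real_)
  }
  stats::cor(u, ystar)
}

#' Inflation regression of adjusted phenotypes on breeding values
#'
#' Ordinary least squares `y* = b0 + b1 (G)EBV + e`; a slope `b1 < 1`
#' indicates inflated (over-dispersed) breeding values, `b1 > 1` deflation.
#'
#' @param ystar adjusted phenotypes of validation animals.
#' @param u breeding values of the same animals.
#' @return named vector `c(b0, b1)`, `NA` when the EBV variance is zero.
#' @export
inflationRegression <- function(ystar, u) {
  if (stats::sd(u) == 0) {
    warning("zero EBV variance; inflation regression undefined")
    return(c(b0 = NA_real_, b1 = NA_real_))
  }
  b1 <- stats::cov(ystar, u) / stats::var(u)
  c(b0 = mean(ystar) - b1 * mean(u), b1 = b1)
}

#' Precompute relationship machinery for one dataset
#'
#' Builds the sparse pedigree inverse, the genotyped-block `A22`, the
#' (blended) VanRaden `G`, and the single-step `H^-1` once, for reuse
#' across validation fits.
#'
#' @param ped a [Pedigree-class].
#' @param geno a [GenotypeData-class] (post-QC), or `NULL` for
#'   pedigree-only work.
#' @param blend blending proportion of `A22` into `G`.
#' @param weights optional per-SNP weights for `G`.
#' @return list: `Ainv`, `A22`, `G`, `Gb`, `Hinv`, `genoIdx`, `p`.
#' @export
buildRelationships <- function(ped, geno = NULL, blend = 0.05,
                               weights = NULL) {
  Ainv <- buildAInverse(ped)
  if (is.null(geno) || length(geno@animals) == 0)
    return(list(Ainv = Ainv, A22 = NULL, G = NULL, Gb = NULL, Hinv = Ainv,
                genoIdx = integer(0), p = NULL))
  genoIdx <- pedigreeIds(ped, geno@animals)
  A22 <- extractA22(ped, genoIdx)
  p <- alleleFrequencies(geno)
  G <- buildG(geno, p, weights = weights)
  Gb <- blendG(G, A22, beta = blend)
  Hinv <- buildHInverse(Ainv, A22, Gb, genoIdx)
  list(Ainv = Ainv, A22 = A22, G = G, Gb = Gb, Hinv = Hinv,
       genoIdx = genoIdx, p = p)
}

#' Run the training/validation study designs
#'
#' Orchestrates the four strategies:
#' \describe{
#'   \item{1}{random k-fold cross-validation over genotyped phenotyped
#'     animals, replicated.}
#'   \item{2}{genotyped full-sib families halved into training and
#'     validation; validation phenotypes removed.}
#'   \item{3}{as 2, but only half of the genotyped training full-sibs keep
#'     their phenotypes.}
#'   \item{4}{as 2, but phenotypes are removed from *all* genotyped
#'     animals; ungenotyped relatives' phenotypes stay and information
#'     flows to the genotyped candidates through `H`.}
#' }
#' For every training set and method the MME are refit and the validation
#' animals scored with predictive ability and the inflation slope, against
#' adjusted phenotypes from the full-data fit.
#'
#' @param ped,geno,pheno dataset pieces ([Pedigree-class],
#'   [GenotypeData-class], data.frame).
#' @param spec the [ModelSpec-class] of the trait under study.
#' @param vc variance components used for fitting (list `sigma2_u`,
#'   `sigma2_p`, `sigma2_e`).
#' @param rel output of [buildRelationships()] (built if missing).
#' @param strategies subset of `1:4`.
#' @param methods `"BLUP"`, `"ssGBLUP"` or both.
#' @param vcMode `"fixed"` (use `vc` for every training set),
#'   `"reestimate"` (EM-REML per training set), or both.
#' @param k,replicates strategy-1 settings.
#' @param seed master seed; all draws derive from it.
#' @param adjust scoring phenotypes: `"nongenetic"` (default) removes all
#'   non-genetic model effects estimated from the full data — fixed
#'   effects and the spawn common-environment effect — so that predictive
#'   ability and the inflation slope measure alignment with genetic merit;
#'   `"fixed"` removes fixed effects only. The two coincide when the model
#'   has no common-environment term. With `"fixed"`, a validation animal's
#'   spawn effect leaks into the score through its co-reared training
#'   sibs, which rewards family-mean (pedigree) predictions and pushes the
#'   inflation slope above 1.
#' @return tidy data.frame: `strategy`, `method`, `vcMode`, `replicate`,
#'   `fold`, `r`, `b1`, `nValidation`.
#' @export
runValidation <- function(ped, geno, pheno, spec, vc,
                          rel = buildRelationships(ped, geno),
                          strategies = c(1, 2), methods = c("BLUP", "ssGBLUP"),
                          vcMode = "fixed", k = 5, replicates = 5, seed = 1,
                          adjust = c("nongenetic", "fixed")) {
  stopifnot(all(strategies %in% 1:4))
  adjust <- match.arg(adjust)
  trait <- spec@trait
  fullDesign <- buildDesign(pheno, spec, ped)
  Kof <- function(m) if (m == "ssGBLUP") rel$Hinv else rel$Ainv
  fullFits <- lapply(stats::setNames(methods, methods), function(m)
    solveMME(fullDesign, Kof(m), vc, method = m))
  ystarFull <- lapply(fullFits, function(f) {
    ys <- adjustedPhenotypes(fullDesign, fixedEffects(f))
    if (adjust == "nongenetic" && !is.null(fullDesign$W))
      ys <- ys - as.numeric(fullDesign$W %*% commonEnv(f))
    ys
  })
  recAnimal <- ped@labels[fullDesign$animals]

  genoLab <- geno@animals
  elig <- intersect(genoLab, pheno$animal[!is.na(pheno[[trait]])])
  if (length(elig) < 4) stop("too few genotyped phenotyped animals")

  scoreFit <- function(fit, m, valLabels) {
    idx <- match(valLabels, recAnimal)
    idx <- idx[!is.na(idx)]
    uv <- ebv(fit)[pedigreeIds(ped, recAnimal[idx])]
    ys <- ystarFull[[m]][idx]
    c(r = predictiveAbility(uv, ys),
      b1 = unname(inflationRegression(ys, uv)["b1"]),
      n = length(idx))
  }

  evalSplit <- function(masked, valLabels, strategy, repl, fold, mode) {
    md <- buildDesign(masked, spec, ped)
    out <- list()
    for (m in methods) {
      vcUse <- vc
      if (mode == "reestimate") {
        est <- emReml(md, Kof(m))
        vcUse <- list(sigma2_u = est$sigma2_u,
                      sigma2_p = if (is.na(est$sigma2_p)) NULL else est$sigma2_p,
                      sigma2_e = est$sigma2_e)
      }
      fit <- solveMME(md, Kof(m), vcUse, method = m)
      sc <- scoreFit(fit, m, valLabels)
      out[[m]] <- data.frame(strategy = strategy, method = m, vcMode = mode,
                             replicate = repl, fold = fold,
                             r = sc[["r"]], b1 = sc[["b1"]],
                             nValidation = sc[["n"]])
    }
    do.call(rbind, out)
  }

  rows <- list()
  ## family membership of eligible animals (sire-dam pair)
  eligIdx <- pedigreeIds(ped, elig)
  fam <- paste(ped@sire[eligIdx], ped@dam[eligIdx], sep = "_")
  names(fam) <- elig
  sibPlan <- fullsibSplit(fam, seed = deriveSeed(seed, "strategy2"))

  for (mode in vcMode) {
    if (1 %in% strategies) {
      plans <- kfoldSplit(elig, k = k, replicates = replicates, seed = seed)
      for (r in seq_along(plans)) {
        for (f in seq_along(plans[[r]])) {
          val <- plans[[r]][[f]]
          masked <- maskPhenotypes(pheno, trait, val)
          rows[[length(rows) + 1]] <- evalSplit(masked, val, 1L, r, f, mode)
        }
      }
    }
    if (2 %in% strategies) {
      masked <- maskPhenotypes(pheno, trait, sibPlan$validation)
      rows[[length(rows) + 1]] <-
        evalSplit(masked, sibPlan$validation, 2L, 1L, 1L, mode)
    }
    if (3 %in% strategies) {
      ## half of the genotyped training full-sibs lose their phenotypes
      set.seed(deriveSeed(seed, "strategy3"))
      dropPh <- character(0)
      for (famMembers in split(sibPlan$training,
                               fam[sibPlan$training])) {
        nKeep <- floor(length(famMembers) / 2)
        dropPh <- c(dropPh,
                    sample(famMembers, length(famMembers) - nKeep))
      }
      masked <- maskPhenotypes(pheno, trait,
                               c(sibPlan$validation, dropPh))
      rows[[length(rows) + 1]] <-
        evalSplit(masked, sibPlan$validation, 3L, 1L, 1L, mode)
    }
    if (4 %in% strategies) {
      masked <- maskPhenotypes(pheno, trait, genoLab)
      rows[[length(rows) + 1]] <-
        evalSplit(masked, sibPlan$validation, 4L, 1L, 1L, mode)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a validation table
#'
#' Strategy-1 folds are first averaged within replicate; the summary then
#' reports the mean and standard error (sd of replicate means / sqrt of
#' replicates) per strategy, method and vc mode. Unreplicated designs get
#' `NA` standard errors.
#'
#' @param results output of [runValidation()].
#' @return data.frame with `meanR`, `seR`, `meanB1`, `seB1`.
#' @export
summarizeValidation <- function(results) {
  key <- interaction(results$strategy, results$method, results$vcMode,
                     drop = TRUE)
  out <- lapply(split(results, key), function(d) {
    byRep <- split(d, d$replicate)
    rs <- vapply(byRep, function(x) mean(x$r), numeric(1))
    bs <- vapply(byRep, function(x) mean(x$b1), numeric(1))
    nr <- length(rs)
    data.frame(strategy = d$strategy[1], method = d$method[1],
               vcMode = d$vcMode[1], replicates = nr,
               meanR = mean(rs),
               seR = if (nr > 1) stats::sd(rs) / sqrt(nr) else NA_real_,
               meanB1 = mean(bs),
               seB1 = if (nr > 1) stats::sd(bs) / sqrt(nr) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$strategy, out$method, out$vcMode), ]
}
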