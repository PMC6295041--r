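#' Parameters of the gene-drop breeding-program simulator
#'
#' Defaults emulate the structure of a family-based catfish breeding
#' program: 29 chromosomes, a down-scaled evenly spaced SNP panel, 100
#' full-sib families of 30 tagged offspring per year-class, heritabilities
#' of 0.27 (harvest weight) and 0.34 (carcass weight), a common-environment
#' variance from shared rearing tanks (15% of phenotypic variance), and
#' partial genotyping (10% of offspring).
#'
#' @param nChrom number of chromosomes.
#' @param chrLenM chromosome length in Morgan.
#' @param nSnps total SNP count (split evenly across chromosomes).
#' @param nQtl number of causal SNPs (drawn among the simulated SNPs).
#' @param nFounders unrelated base animals.
#' @param familiesPerYear full-sib families per year-class.
#' @param offspringPerFamily tagged offspring per family.
#' @param nYears number of year-classes after the base generation.
#' @param genotypedFraction fraction of offspring genotyped.
#' @param h2 per-trait heritability (harvest weight, carcass weight).
#' @param c2 common-environment fraction of phenotypic variance.
#' @param rG genetic correlation between the two traits.
#' @param totalVar phenotypic variance (g^2) per trait.
#' @param trait2Fraction fraction of offspring with a carcass record
#'   (processing is destructive, so only a subset is measured).
#' @param nPonds grow-out ponds per year-class.
#' @param selection select broodstock on a standardized phenotype index
#'   (`TRUE`) or at random (`FALSE`, the default, which keeps validation
#'   calibration unbiased).
#' @param selectFraction fraction of a year-class kept as broodfish.
#' @param maxFamilyShare cap on the share of selected broodfish from any
#'   single full-sib family.
#' @param mafFloor lower bound of founder allele frequencies.
#' @param spectrum founder allele-frequency spectrum: `"uniform"` or
#'   `"ushaped"`.
#' @param founderNe effective size of the ancestral population whose drift
#'   builds linkage disequilibrium into the founder haplotypes (the study
#'   population has a small Ne of about 27); `0` draws founders in linkage
#'   equilibrium.
#' @param founderGens generations of ancestral random mating before the
#'   founders are sampled.
#' @param cmPerMb map scale used to lay SNPs onto physical positions.
#' @param bigQtl if `TRUE`, one QTL is planted with 20% of the additive
#'   genetic variance (for planted-signal association tests).
#' @return named list of parameters.
#' @export
simParams <- function(nChrom = 29, chrLenM = 1, nSnps = 2000, nQtl = 300,
                      nFounders = 250, familiesPerYear = 100,
                      offspringPerFamily = 30, nYears = 1,
                      genotypedFraction = 0.10,
                      h2 = c(0.27, 0.34), c2 = 0.15, rG = 0.5,
                      totalVar = c(22500, 2500), trait2Fraction = 0.25,
                      nPonds = 4, selection = FALSE, selectFraction = 0.10,
                      maxFamilyShare = 0.10, mafFloor = 0.05,
                      spectrum = c("uniform", "ushaped"), cmPerMb = 1,
                      bigQtl = FALSE, founderNe = 30, founderGens = 40) {
  spectrum <- match.arg(spectrum)
  if (any(h2 + c2 >= 1)) stop("variance fractions must sum to < 1")
  stopifnot(nChrom > 0, nSnps >= nChrom, nQtl <= nSnps, nFounders >= 2,
            familiesPerYear > 0, offspringPerFamily > 0, nYears > 0)
  as.list(environment())
}

#' Evenly spaced SNP map
#'
#' Lays `nSnps` SNPs evenly over `nChrom` chromosomes; physical length
#' follows from the genetic length through the `cmPerMb` scale.
#'
#' @param params a [simParams()] list.
#' @return `GRanges` map, names `snp1..snpM`.
#' @export
simMap <- function(params) {
  perChr <- rep(params$nSnps %/% params$nChrom, params$nChrom)
  extra <- params$nSnps %% params$nChrom
  if (extra > 0) perChr[seq_len(extra)] <- perChr[seq_len(extra)] + 1L
  chrBp <- params$chrLenM * 100e6 / params$cmPerMb
  gr <- GenomicRanges::GRanges(
    seqnames = rep(paste0("chr", seq_len(params$nChrom)), perChr),
    ranges = IRanges::IRanges(
      start = unlist(lapply(perChr, function(m)
        round(seq(chrBp / (m + 1), chrBp * m / (m + 1), length.out = m)))),
      width = 1))
  names(gr) <- paste0("snp", seq_along(gr))
  gr
}

#' Simulate founder haplotypes
#'
#' Base allele frequencies are drawn from a uniform or U-shaped
#' (Beta(1/2,1/2)) spectrum truncated at `mafFloor`. With
#' `params$founderNe > 0`, founder haplotypes are then sampled from a small
#' ancestral population after `params$founderGens` generations of random
#' mating, which builds realistic linkage disequilibrium (the study
#' population's effective size is small); with `founderNe = 0` founders
#' are in linkage equilibrium.
#'
#' @param params a [simParams()] list.
#' @param nFounders number of founders to draw haplotypes for (defaults to
#'   `params$nFounders`).
#' @return list: `haps` (`2 nFounders x nSnps` 0/1 matrix), `p` (realized
#'   founder allele frequencies), `map` (`GRanges`).
#' @export
simulateFounders <- function(params, nFounders = params$nFounders) {
  m <- params$nSnps
  p <- switch(params$spectrum,
    uniform = stats::runif(m, params$mafFloor, 1 - params$mafFloor),
    ushaped = {
      x <- stats::rbeta(m, 0.5, 0.5)
      pmin(pmax(x, params$mafFloor), 1 - params$mafFloor)
    })
  map <- simMap(params)
  if (params$founderNe > 0 && params$founderGens > 0) {
    ne <- params$founderNe
    anc <- randomMatingPedigree(ne, params$founderGens)
    nAnc <- nAnimals(anc)
    ## append the founders as offspring of the last ancestral generation
    lastGen <- which(anc@yearClass == max(anc@yearClass))
    males <- lastGen[seq_along(lastGen) %% 2 == 1]
    females <- lastGen[seq_along(lastGen) %% 2 == 0]
    sire <- c(anc@sire, sample(males, nFounders, replace = TRUE))
    dam <- c(anc@dam, sample(females, nFounders, replace = TRUE))
    full <- new("Pedigree", sire = sire, dam = dam,
                labels = c(anc@labels, paste0("fnd", seq_len(nFounders))),
                yearClass = c(anc@yearClass,
                              rep(max(anc@yearClass) + 1L, nFounders)))
    base <- matrix(stats::rbinom(2 * ne * m, 1, rep(p, each = 2 * ne)),
                   nrow = 2 * ne, ncol = m)
    chrNames <- unique(as.character(GenomicRanges::seqnames(map)))
    allHaps <- .gene_drop(full@sire, full@dam, base,
                          GenomicRanges::start(map) * params$cmPerMb / 1e8,
                          match(as.character(GenomicRanges::seqnames(map)),
                                chrNames),
                          rep(params$chrLenM, length(chrNames)), p)
    rows <- as.vector(rbind(2 * (nAnc + seq_len(nFounders)) - 1,
                            2 * (nAnc + seq_len(nFounders))))
    haps <- allHaps[rows, , drop = FALSE]
  } else {
    haps <- matrix(stats::rbinom(2 * nFounders * m, 1,
                                 rep(p, each = 2 * nFounders)),
                   nrow = 2 * nFounders, ncol = m)
  }
  list(haps = haps, p = colMeans(haps), map = map)
}

#' Simulate a breeding-program pedigree
#'
#' Founders form the base; each year-class mates broodstock drawn from the
#' previous generation (random or index-selected), one full-sib family per
#' sire-dam pair, avoiding full-sib matings and capping any family's share
#' of the broodstock.
#'
#' @param params a [simParams()] list.
#' @param index optional per-animal selection criterion (labels as names)
#'   used when `params$selection` is `TRUE`; when absent, selection falls
#'   back to random.
#' @return list: `ped` ([Pedigree-class]), `meta` data.frame
#'   (`animal`, `year`, `spawn`, `sex`, `family`).
#' @export
simulatePedigree <- function(params, index = NULL) {
  nF <- params$nFounders
  labels <- paste0("F", seq_len(nF))
  sire <- rep("0", nF)
  dam <- rep("0", nF)
  sex <- rep(c("M", "F"), length.out = nF)
  year <- rep(0L, nF)
  spawn <- rep(NA_character_, nF)
  family <- rep(paste0("base", seq_len(nF)), 1)

  prevLabels <- labels
  prevSex <- sex
  prevFamily <- family
  for (yr in seq_len(params$nYears)) {
    nFam <- params$familiesPerYear
    males <- prevLabels[prevSex == "M"]
    females <- prevLabels[prevSex == "F"]
    pickParents <- function(cands) {
      if (params$selection && !is.null(index)) {
        sc <- index[cands]
        sc[is.na(sc)] <- -Inf
        cands <- cands[order(-sc)]
      } else {
        cands <- sample(cands)
      }
      ## cap the share of any single full-sib family
      cap <- max(1L, ceiling(params$maxFamilyShare * nFam))
      fams <- prevFamily[match(cands, prevLabels)]
      keep <- unlist(lapply(split(seq_along(cands), fams),
                            function(ix) ix[seq_len(min(length(ix), cap))]))
      cands[sort(keep)][seq_len(min(nFam, length(keep)))]
    }
    sires <- pickParents(males)
    dams <- pickParents(females)
    nFam <- min(nFam, length(sires), length(dams))
    sires <- sires[seq_len(nFam)]
    dams <- sample(dams)[seq_len(nFam)]
    ## avoid full-sib matings: reshuffle dams paired with a full sib
    famOf <- function(x) prevFamily[match(x, prevLabels)]
    for (tries in 1:20) {
      clash <- which(famOf(sires) == famOf(dams))
      if (length(clash) <= 1) break
      dams[clash] <- sample(dams[clash])
    }
    nOff <- params$offspringPerFamily
    offLab <- paste0("Y", yr, "_", rep(seq_len(nFam), each = nOff), "_",
                     rep(seq_len(nOff), nFam))
    labels <- c(labels, offLab)
    sire <- c(sire, rep(sires, each = nOff))
    dam <- c(dam, rep(dams, each = nOff))
    offSex <- sample(c("M", "F"), nFam * nOff, replace = TRUE)
    sex <- c(sex, offSex)
    year <- c(year, rep(yr, nFam * nOff))
    offSpawn <- paste0("spawn_Y", yr, "_", rep(seq_len(nFam), each = nOff))
    spawn <- c(spawn, offSpawn)
    family <- c(family, offSpawn)
    prevLabels <- offLab
    prevSex <- offSex
    prevFamily <- offSpawn
  }
  ped <- Pedigree(labels, sire, dam, yearClass = year)
  meta <- data.frame(animal = labels, year = year, spawn = spawn,
                     sex = sex, family = family,
                     stringsAsFactors = FALSE)
  list(ped = ped, meta = meta)
}

#' Closed random-mating population pedigree
#'
#' Constant census size, discrete generations, random pair mating between
#' the sexes (no selfing); a drift reference for effective-population-size
#' checks.
#'
#' @param N census size per generation.
#' @param generations number of generations after the founders.
#' @return a [Pedigree-class] with year-class = generation.
#' @export
randomMatingPedigree <- function(N, generations) {
  labels <- paste0("G0_", seq_len(N))
  sire <- rep("0", N)
  dam <- rep("0", N)
  sex <- rep(c("M", "F"), length.out = N)
  year <- rep(0L, N)
  prev <- labels
  prevSex <- sex
  for (g in seq_len(generations)) {
    males <- prev[prevSex == "M"]
    females <- prev[prevSex == "F"]
    lab <- paste0("G", g, "_", seq_len(N))
    labels <- c(labels, lab)
    sire <- c(sire, sample(males, N, replace = TRUE))
    dam <- c(dam, sample(females, N, replace = TRUE))
    newSex <- rep(c("M", "F"), length.out = N)
    sex <- c(sex, newSex)
    year <- c(year, rep(g, N))
    prev <- lab
    prevSex <- newSex
  }
  Pedigree(labels, sire, dam, yearClass = year)
}

#' Drop founder haplotypes through a pedigree
#'
#' Each meiosis samples a Poisson number of crossovers per chromosome
#' (mean = genetic length in Morgan, Haldane's no-interference model) at
#' uniform positions. Unknown parents contribute haplotypes drawn from the
#' founder allele frequencies.
#'
#' @param ped a sorted [Pedigree-class]; animals with both parents unknown
#'   consume founder haplotypes in pedigree order.
#' @param founders output of [simulateFounders()] (enough haplotypes for
#'   all founders in `ped`).
#' @param params a [simParams()] list.
#' @return list: `dosage` (all animals x SNPs), `haps`
#'   (`2n x nSnps` 0/1 matrix).
#' @export
geneDrop <- function(ped, founders, params) {
  map <- founders$map
  chrNames <- unique(as.character(GenomicRanges::seqnames(map)))
  chrIdx <- match(as.character(GenomicRanges::seqnames(map)), chrNames)
  posM <- GenomicRanges::start(map) * params$cmPerMb / 1e8
  chrLen <- rep(params$chrLenM, length(chrNames))
  haps <- .gene_drop(ped@sire, ped@dam, founders$haps, posM, chrIdx,
                     chrLen, founders$p)
  n <- nAnimals(ped)
  dosage <- haps[seq(1, 2 * n, by = 2), , drop = FALSE] +
    haps[seq(2, 2 * n, by = 2), , drop = FALSE]
  rownames(dosage) <- ped@labels
  colnames(dosage) <- names(map)
  list(dosage = dosage, haps = haps)
}

#' Simulate phenotypes under the two-trait animal model
#'
#' True breeding values are sums of QTL dosages times effects (Gaussian
#' effects; optionally one large QTL carrying 20% of the additive
#' variance), scaled so the realized additive variance matches the target.
#' Phenotypes add year-sex-pond cell effects, an age-within-sex covariate
#' (harvest weight), a body-weight-within-year-sex covariate (carcass
#' weight), a spawn-group common-environment effect and a residual, with
#' variances set by `h2`, `c2` and `totalVar`.
#'
#' @param ped a [Pedigree-class].
#' @param meta pedigree metadata from [simulatePedigree()].
#' @param dosage dosage matrix for all animals (from [geneDrop()]).
#' @param params a [simParams()] list.
#' @return list: `pheno` (records for offspring), `truth` (per-animal TBV
#'   per trait, QTL indices/effects, variance components).
#' @export
simulatePhenotypes <- function(ped, meta, dosage, params) {
  n <- nAnimals(ped)
  m <- ncol(dosage)
  h2 <- params$h2
  c2 <- params$c2
  tv <- params$totalVar
  sigU <- h2 * tv
  sigP <- c2 * tv
  sigE <- (1 - h2 - c2) * tv

  qtl <- sort(sample(m, params$nQtl))
  a1 <- stats::rnorm(params$nQtl)
  a2 <- params$rG * a1 + sqrt(1 - params$rG^2) * stats::rnorm(params$nQtl)
  bigQtlSnp <- NA_integer_
  if (params$bigQtl) {
    ## plant one QTL holding ~20% of the additive variance
    Q <- dosage[, qtl, drop = FALSE]
    vq <- apply(Q, 2, stats::var)
    vloc <- vq * a1^2
    k <- which.max(vq)
    a1[k] <- sqrt(0.25 * sum(vloc[-k]) / max(vq[k], 1e-9))
    a2[k] <- a1[k]
    bigQtlSnp <- qtl[k]
  }
  scaleTo <- function(raw, target) {
    v <- stats::var(raw)
    if (v <= 0) return(list(tbv = raw * 0, f = 0))
    f <- sqrt(target / v)
    list(tbv = (raw - mean(raw)) * f, f = f)
  }
  Q <- dosage[, qtl, drop = FALSE]
  s1 <- scaleTo(as.numeric(Q %*% a1), sigU[1])
  s2 <- scaleTo(as.numeric(Q %*% a2), sigU[2])
  tbv1 <- s1$tbv
  tbv2 <- s2$tbv

  off <- which(meta$year > 0)
  rec <- meta[off, , drop = FALSE]
  nr <- nrow(rec)
  rec$pond <- sample(paste0("P", seq_len(params$nPonds)), nr, replace = TRUE)
  rec$age <- round(stats::runif(nr, 391, 620))
  rec$ysp <- factor(paste(rec$year, rec$sex, rec$pond, sep = "_"))
  rec$yearSex <- factor(paste(rec$year, rec$sex, sep = "_"))

  cellSd1 <- 0.3 * sqrt(tv[1])
  cell1 <- stats::rnorm(nlevels(rec$ysp), 0, cellSd1)
  names(cell1) <- levels(rec$ysp)
  ageSlope <- c(M = 0.8, F = 1.0) * sqrt(tv[1]) / 150
  spawnLevels <- unique(rec$spawn)
  pe1 <- stats::rnorm(length(spawnLevels), 0, sqrt(sigP[1]))
  names(pe1) <- spawnLevels
  e1 <- stats::rnorm(nr, 0, sqrt(sigE[1]))
  mu1 <- 700
  rec$harvestWeight <- mu1 + cell1[as.character(rec$ysp)] +
    ageSlope[rec$sex] * (rec$age - 500) + tbv1[pedigreeIds(ped, rec$animal)] +
    pe1[rec$spawn] + e1

  ## carcass weight on a processed subset, body weight as covariate
  rec$bodyWeight <- rec$harvestWeight
  cellSd2 <- 0.3 * sqrt(tv[2])
  cell2 <- stats::rnorm(nlevels(rec$ysp), 0, cellSd2)
  names(cell2) <- levels(rec$ysp)
  bwSlope <- stats::rnorm(nlevels(rec$yearSex), 0.55, 0.05) * sqrt(tv[2]) / sqrt(tv[1])
  names(bwSlope) <- levels(rec$yearSex)
  pe2 <- stats::rnorm(length(spawnLevels), 0, sqrt(sigP[2]))
  names(pe2) <- spawnLevels
  e2 <- stats::rnorm(nr, 0, sqrt(sigE[2]))
  carc <- 220 + cell2[as.character(rec$ysp)] +
    bwSlope[as.character(rec$yearSex)] * (rec$bodyWeight - mu1) +
    tbv2[pedigreeIds(ped, rec$animal)] + pe2[rec$spawn] + e2
  processed <- sort(sample(nr, round(params$trait2Fraction * nr)))
  rec$carcassWeight <- NA_real_
  rec$carcassWeight[processed] <- carc[processed]

  truth <- list(tbv = cbind(harvestWeight = tbv1, carcassWeight = tbv2),
                qtl = qtl, effects = cbind(a1 * s1$f, a2 * s2$f),
                bigQtlSnp = bigQtlSnp,
                vc = list(
                  harvestWeight = list(sigma2_u = sigU[1], sigma2_p = sigP[1],
                                       sigma2_e = sigE[1]),
                  carcassWeight = list(sigma2_u = sigU[2], sigma2_p = sigP[2],
                                       sigma2_e = sigE[2])),
                realizedVarU = c(stats::var(tbv1), stats::var(tbv2)))
  list(pheno = rec, truth = truth)
}

#' Simulate a complete dataset
#'
#' Pedigree, gene-dropped genotypes, two-trait phenotypes and truth, with
#' a genotyped subset of offspring. All randomness derives from `seed`
#' through [deriveSeed()], so reruns are reproducible.
#'
#' @param params a [simParams()] list.
#' @param seed master seed.
#' @return a [SimulatedDataset-class].
#' @export
simulateDataset <- function(params = simParams(), seed = 1) {
  set.seed(deriveSeed(seed, "pedigree"))
  pg <- simulatePedigree(params)
  ped <- pg$ped
  set.seed(deriveSeed(seed, "founders"))
  founders <- simulateFounders(
    params, nFounders = sum(ped@sire == 0L & ped@dam == 0L))
  set.seed(deriveSeed(seed, "genedrop"))
  gd <- geneDrop(ped, founders, params)
  set.seed(deriveSeed(seed, "phenotypes"))
  sim <- simulatePhenotypes(ped, pg$meta, gd$dosage, params)

  off <- sim$pheno$animal
  set.seed(deriveSeed(seed, "genotyped"))
  genoAnimals <- sort(sample(off, round(params$genotypedFraction * length(off))))
  geno <- GenotypeData(gd$dosage[genoAnimals, , drop = FALSE], founders$map,
                       animals = genoAnimals)
  new("SimulatedDataset", ped = ped, geno = geno, pheno = sim$pheno,
      truth = c(sim$truth, list(seed = seed)), params = params)
}

#' Simulate a trait exactly under the fitted animal model
#'
#' Draws `u ~ N(0, sigma2_u K)`, spawn effects `p ~ N(0, sigma2_p I)` and
#' residuals, and writes `mu + u + p + e` as a new trait column. With `K`
#' the same relationship used in the evaluation (A or H), the fit is
#' correctly specified, which is the setting in which breeding-value
#' calibration (inflation slope near 1) is expected to hold. Intended for
#' calibration experiments.
#'
#' @param ped a [Pedigree-class].
#' @param K dense relationship matrix over all pedigree animals.
#' @param vc list `sigma2_u`, `sigma2_p`, `sigma2_e`.
#' @param pheno record table (animal, spawn columns) whose trait column is
#'   replaced.
#' @param trait name of the column to write.
#' @param mu intercept.
#' @return list: `pheno` (with the new trait), `u` (true breeding values,
#'   all animals).
#' @export
simulateModelTrait <- function(ped, K, vc, pheno, trait = "y", mu = 500) {
  n <- nAnimals(ped)
  stopifnot(nrow(K) == n)
  R <- chol(K + diag(1e-8, n))
  u <- sqrt(vc$sigma2_u) * as.numeric(t(R) %*% stats::rnorm(n))
  spawns <- unique(pheno$spawn)
  pe <- stats::rnorm(length(spawns), 0, sqrt(vc$sigma2_p))
  names(pe) <- spawns
  e <- stats::rnorm(nrow(pheno), 0, sqrt(vc$sigma2_e))
  pheno[[trait]] <- mu + u[pedigreeIds(ped, pheno$animal)] +
    pe[pheno$spawn] + e
  list(pheno = pheno, u = u)
}

#' Default model specifications for the simulated traits
#'
#' Harvest weight: year-sex-pond cells plus age nested within sex.
#' Carcass weight: year-sex-pond cells plus body weight nested within
#' year-sex (the residual-carcass-weight model).
#'
#' @return named list of [ModelSpec-class] objects.
#' @export
defaultModelSpecs <- function() {
  list(harvestWeight = modelSpec("harvestWeight", ~ ysp + sex:age),
       carcassWeight = modelSpec("carcassWeight", ~ ysp + yearSex:bodyWeight))
}

#' Write a simulated dataset to plain-text files
#'
#' Pedigree, phenotypes, dosage matrix, SNP map and truth as CSV/TSV, plus
#' a JSON manifest with the seed and a parameter digest.
#'
#' @param sim a [SimulatedDataset-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ped <- sim@ped
  utils::write.csv(
    data.frame(animal = ped@labels,
               sire = ifelse(ped@sire == 0L, "0", ped@labels[pmax(ped@sire, 1L)]),
               dam = ifelse(ped@dam == 0L, "0", ped@labels[pmax(ped@dam, 1L)]),
               year_class = ped@yearClass),
    file.path(dir, "pedigree.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(sim@pheno, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  dos <- sim@geno@dosage
  utils::write.table(data.frame(animal = rownames(dos), dos,
                                check.names = FALSE),
                     file.path(dir, "genotypes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  map <- sim@geno@map
  utils::write.csv(
    data.frame(snp = names(map),
               chrom = as.character(GenomicRanges::seqnames(map)),
               pos = GenomicRanges::start(map)),
    file.path(dir, "snp_map.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(animal = ped@labels, sim@truth$tbv, check.names = FALSE),
    file.path(dir, "truth.csv"), row.names = FALSE, quote = FALSE)
  paramPath <- file.path(dir, "params.json")
  jsonlite::write_json(sim@params, paramPath, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = sim@truth$seed,
         params_md5 = unname(tools::md5sum(paramPath)),
         files = c("pedigree.csv", "phenotypes.csv", "genotypes.tsv",
                   "snp_map.csv", "truth.csv", "params.json")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read back a dataset written by [writeDataset()]
#'
#' @param dir dataset directory.
#' @return a [SimulatedDataset-class] (truth restricted to what the files
#'   carry).
#' @export
readDataset <- function(dir) {
  ped <- readPedigree(file.path(dir, "pedigree.csv"))
  pheno <- utils::read.csv(file.path(dir, "phenotypes.csv"),
                           stringsAsFactors = FALSE)
  for (v in c("ysp", "yearSex")) pheno[[v]] <- factor(pheno[[v]])
  g <- utils::read.table(file.path(dir, "genotypes.tsv"), header = TRUE,
                         sep = "\t", check.names = FALSE)
  dos <- as.matrix(g[, -1, drop = FALSE])
  rownames(dos) <- g$animal
  map <- utils::read.csv(file.path(dir, "snp_map.csv"),
                         stringsAsFactors = FALSE)
  geno <- GenotypeData(dos, map, animals = g$animal)
  tr <- utils::read.csv(file.path(dir, "truth.csv"), check.names = FALSE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  params <- jsonlite::read_json(file.path(dir, "params.json"),
                                simplifyVector = TRUE)
  new("SimulatedDataset", ped = ped, geno = geno, pheno = pheno,
      truth = list(tbv = as.matrix(tr[, -1, drop = FALSE]),
                   seed = manifest$seed),
      params = params)
}
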