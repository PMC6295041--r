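test_that("founder haplotypes respect counts, determinism and the spectrum", {
  p <- simParams(nChrom = 2, nSnps = 50, nQtl = 10, nFounders = 2,
                 founderNe = 0)
  set.seed(1)
  f <- simulateFounders(p, nFounders = 2)
  expect_equal(dim(f$haps), c(4L, 50L))
  set.seed(1)
  f2 <- simulateFounders(p, nFounders = 2)
  expect_identical(f$haps, f2$haps)

  ## linkage-equilibrium frequencies stay within the truncated band
  p2 <- simParams(nSnps = 4000, nQtl = 100, nFounders = 400, founderNe = 0,
                  mafFloor = 0.1)
  set.seed(2)
  f3 <- simulateFounders(p2, nFounders = 400)
  expect_gt(min(f3$p), 0.05)   # sampling wiggle around the 0.1 floor
  expect_lt(max(f3$p), 0.95)
  ## close to uniform(0.1, 0.9): mean 0.5, sd 0.8/sqrt(12)
  expect_equal(mean(f3$p), 0.5, tolerance = 0.02)
  expect_equal(sd(f3$p), 0.8 / sqrt(12), tolerance = 0.03)
})

test_that("zero-length chromosomes transmit intact parental haplotypes", {
  p <- simParams(nChrom = 1, chrLenM = 0, nSnps = 30, nQtl = 5,
                 nFounders = 2, founderNe = 0)
  ped <- Pedigree(1:3, c(0, 0, 1), c(0, 0, 2))
  set.seed(3)
  f <- simulateFounders(p, nFounders = 2)
  gd <- geneDrop(ped, f, p)
  childHap1 <- gd$haps[5, ]
  sireHaps <- gd$haps[1:2, ]
  expect_true(all(childHap1 == sireHaps[1, ]) ||
                all(childHap1 == sireHaps[2, ]))
})

test_that("offspring dosages respect Mendelian bounds", {
  prm <- simParams(nChrom = 3, nSnps = 90, nQtl = 20, nFounders = 30,
                   familiesPerYear = 10, offspringPerFamily = 8,
                   founderGens = 10)
  set.seed(36)
  pg <- simulatePedigree(prm)
  ped <- pg$ped
  f <- simulateFounders(prm, nFounders = sum(ped@sire == 0L & ped@dam == 0L))
  gd <- geneDrop(ped, f, prm)
  d <- gd$dosage
  off <- which(ped@sire > 0L & ped@dam > 0L)
  set.seed(1)
  for (a in sample(off, 25)) {
    ds <- d[ped@sire[a], ]; dd <- d[ped@dam[a], ]; dc <- d[a, ]
    lo <- (ds == 2) + (dd == 2)
    hi <- 2 - ((ds == 0) + (dd == 0))
    expect_true(all(dc >= lo & dc <= hi))
  }
})

test_that("recombination follows Haldane's map-distance expectation", {
  ## one heterozygous sire with known phase, many offspring
  n <- 2500
  ped <- Pedigree(seq_len(n + 2), c(0, 0, rep(1, n)), c(0, 0, rep(2, n)))
  prm <- simParams(nChrom = 1, chrLenM = 0.5, nSnps = 2, nQtl = 1,
                   nFounders = 2, founderNe = 0)
  founders <- list(haps = rbind(c(1, 1), c(0, 0), c(0, 0), c(0, 0)),
                   p = c(0.5, 0.5), map = simMap(prm))
  set.seed(4)
  gd <- geneDrop(ped, founders, prm)
  ## paternal gametes of the offspring are rows 2i-1 for animals 3..n+2
  pat <- gd$haps[2 * (3:(n + 2)) - 1, ]
  recomb <- mean(pat[, 1] != pat[, 2])
  dM <- diff(GenomicRanges::start(founders$map)) / 1e8
  cExp <- (1 - exp(-2 * dM)) / 2
  expect_equal(recomb, cExp, tolerance = 0.035)
})

test_that("phenotypes scale to the requested architecture", {
  ## zero heritability: no additive variance at all
  p0 <- simParams(nChrom = 2, nSnps = 60, nQtl = 20, nFounders = 40,
                  familiesPerYear = 12, offspringPerFamily = 10,
                  h2 = c(0, 0), founderGens = 5)
  sim0 <- simulateDataset(p0, seed = 37)
  expect_equal(var(sim0@truth$tbv[, 1]), 0)

  ## regression of phenotype on true breeding value is ~1
  sim <- smallSim(seed = 38, familiesPerYear = 40, offspringPerFamily = 25)
  tb <- sim@truth$tbv[pedigreeIds(sim@ped, sim@pheno$animal), 1]
  fit <- lm(sim@pheno$harvestWeight ~ tb + sim@pheno$ysp)
  expect_equal(unname(coef(fit)["tb"]), 1, tolerance = 0.1)
  ## realized additive variance is the configured target
  expect_equal(var(sim@truth$tbv[, 1]),
               sim@truth$vc$harvestWeight$sigma2_u, tolerance = 1e-6)
})

test_that("datasets round-trip through disk byte-faithfully", {
  sim <- smallSim(seed = 39, nSnps = 60, nFounders = 30,
                  familiesPerYear = 8, offspringPerFamily = 6)
  dir <- file.path(tempdir(), "dsround")
  writeDataset(sim, dir)
  back <- readDataset(dir)
  expect_equal(dosages(back@geno), dosages(sim@geno))
  expect_equal(back@ped@sire, sim@ped@sire)
  expect_equal(back@pheno$harvestWeight, sim@pheno$harvestWeight)
  expect_equal(unname(back@truth$tbv[, 1]), unname(sim@truth$tbv[, 1]))
  expect_equal(nrow(back@truth$tbv), nAnimals(sim@ped))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 39)

  ## the same seed reproduces the dataset exactly
  sim2 <- smallSim(seed = 39, nSnps = 60, nFounders = 30,
                   familiesPerYear = 8, offspringPerFamily = 6)
  expect_identical(dosages(sim2@geno), dosages(sim@geno))
  expect_identical(sim2@pheno$harvestWeight, sim@pheno$harvestWeight)
})

test_that("the breeding pedigree respects the mating constraints", {
  p <- simParams(nFounders = 60, familiesPerYear = 20,
                 offspringPerFamily = 10, nYears = 2, nSnps = 29,
                 nQtl = 10)
  set.seed(40)
  pg <- simulatePedigree(p)
  ped <- pg$ped
  off <- which(ped@sire > 0)
  fam <- paste(ped@sire[off], ped@dam[off], sep = "_")
  ## constant family size, one spawn per family
  expect_true(all(table(fam) == 10))
  ## no full-sib matings: sire and dam of any family are not full sibs
  pairs <- unique(cbind(ped@sire[off], ped@dam[off]))
  sibKey <- function(i) paste(ped@sire[i], ped@dam[i], sep = "_")
  clashes <- sum(ped@sire[pairs[, 1]] > 0 &
                   sibKey(pairs[, 1]) == sibKey(pairs[, 2]))
  expect_equal(clashes, 0)
})
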