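test_that("design matrices encode factors, nesting and record maps", {
  ped <- Pedigree(1:4, c(0, 0, 0, 0), c(0, 0, 0, 0))
  ph <- data.frame(animal = c(1, 2, 3), y = c(10, 12, NA),
                   cell = factor(c("A", "A", "B")), age = c(400, 500, 450),
                   spawn = c("f1", "f1", "f2"))
  spec <- modelSpec("y", ~ cell + age, spawn = "spawn")
  des <- buildDesign(ph, spec, ped)
  ## the NA record is excluded from y but its animal stays in u columns
  expect_equal(length(des$y), 2L)
  expect_equal(dim(des$Z), c(2L, 4L))
  expect_equal(des$animals, c(1L, 2L))
  ## X b reproduces hand-built dummy coding
  b <- c(2, 5)  # intercept + age (cell B dropped with its record)
  expect_equal(as.numeric(des$X %*% b), 2 + 5 * c(400, 500))
  ## unknown animal is fatal
  ph2 <- ph; ph2$animal[1] <- 99
  expect_error(buildDesign(ph2, spec, ped), "not in pedigree")
})

test_that("two unrelated phenotyped animals give the closed-form solution", {
  ped <- Pedigree(1:2, c(0, 0), c(0, 0))
  ph <- data.frame(animal = 1:2, y = c(8, 12))
  spec <- modelSpec("y", ~ 1, spawn = NA)
  des <- buildDesign(ph, spec, ped)
  lambda <- 3
  fit <- solveMME(des, buildAInverse(ped),
                  list(sigma2_u = 1, sigma2_e = lambda))
  expect_equal(unname(fixedEffects(fit)), 10, tolerance = 1e-10)
  expect_equal(ebv(fit), (c(8, 12) - 10) / (1 + lambda), tolerance = 1e-10)
})

test_that("the shrinkage limit reduces to generalized least squares", {
  set.seed(8)
  ped <- randomPedigree(30)
  ph <- data.frame(animal = 1:30, y = rnorm(30, 50),
                   g = factor(rep(c("A", "B"), 15)))
  spec <- modelSpec("y", ~ g, spawn = NA)
  des <- buildDesign(ph, spec, ped)
  fit <- solveMME(des, buildAInverse(ped),
                  list(sigma2_u = 1e-10, sigma2_e = 1))
  expect_lt(max(abs(ebv(fit))), 1e-6)
  ols <- coef(lm(y ~ g, ph))
  expect_equal(unname(fixedEffects(fit)), unname(ols), tolerance = 1e-5)
})

test_that("PCG agrees with the dense direct solve", {
  set.seed(99)
  sim <- smallSim(seed = 5)
  spec <- defaultModelSpecs()$harvestWeight
  vc <- sim@truth$vc$harvestWeight
  des <- buildDesign(sim@pheno, spec, sim@ped)
  Ainv <- buildAInverse(sim@ped)
  fd <- solveMME(des, Ainv, vc, solver = "direct")
  fp <- solveMME(des, Ainv, vc, solver = "pcg", tol = 1e-10)
  expect_lt(max(abs(ebv(fd) - ebv(fp))) / max(abs(ebv(fd))), 1e-6)
  expect_lt(max(abs(fixedEffects(fd) - fixedEffects(fp))) /
              max(abs(fixedEffects(fd))), 1e-6)
  expect_equal(fp@diagnostics$solver, "pcg")
})

test_that("solutions satisfy the normal-equation identities", {
  sim <- smallSim(seed = 6)
  spec <- defaultModelSpecs()$harvestWeight
  des <- buildDesign(sim@pheno, spec, sim@ped)
  fit <- solveMME(des, buildAInverse(sim@ped), sim@truth$vc$harvestWeight)
  resid <- des$y - as.numeric(des$X %*% fixedEffects(fit)) -
    as.numeric(des$Z %*% ebv(fit)) - as.numeric(des$W %*% commonEnv(fit))
  ## residuals weighted by each fixed-effect column sum to zero
  expect_lt(max(abs(crossprod(des$X, resid))), 1e-6)
})

test_that("solutions are invariant to record order", {
  sim <- smallSim(seed = 7)
  spec <- defaultModelSpecs()$harvestWeight
  vc <- sim@truth$vc$harvestWeight
  Ainv <- buildAInverse(sim@ped)
  des1 <- buildDesign(sim@pheno, spec, sim@ped)
  set.seed(1); perm <- sample(nrow(sim@pheno))
  des2 <- buildDesign(sim@pheno[perm, ], spec, sim@ped)
  f1 <- solveMME(des1, Ainv, vc)
  f2 <- solveMME(des2, Ainv, vc)
  expect_equal(ebv(f1), ebv(f2), tolerance = 1e-8)
})

test_that("ssGBLUP collapses to pedigree BLUP without genomic information", {
  sim <- smallSim(seed = 8)
  spec <- defaultModelSpecs()$harvestWeight
  vc <- sim@truth$vc$harvestWeight
  des <- buildDesign(sim@pheno, spec, sim@ped)
  relEmpty <- buildRelationships(sim@ped, NULL)
  fa <- solveMME(des, relEmpty$Ainv, vc)
  fh <- solveMME(des, relEmpty$Hinv, vc, method = "ssGBLUP")
  expect_identical(ebv(fa), ebv(fh))

  ## replacing the blended G by A22 makes the genomic block vanish
  qc <- snpQc(sim@geno)
  gi <- pedigreeIds(sim@ped, genotypedAnimals(qc$geno))
  A22 <- extractA22(sim@ped, gi)
  Hinv <- buildHInverse(relEmpty$Ainv, A22, A22, gi)
  fh2 <- solveMME(des, Hinv, vc, method = "ssGBLUP")
  expect_lt(max(abs(ebv(fa) - ebv(fh2))), 1e-6)
})

test_that("adjusted phenotypes subtract the full-data fixed effects", {
  des <- list(y = c(5, 7), X = cbind(1, c(0, 1)))
  expect_equal(adjustedPhenotypes(des, c(0, 0)), c(5, 7))
  expect_equal(adjustedPhenotypes(des, c(6, 0)), c(-1, 1))
  expect_equal(adjustedPhenotypes(des, c(1, 2)), c(4, 4))
  expect_error(adjustedPhenotypes(des, 1), "does not match")
})

test_that("parent averages follow the pedigree with unknowns as zero", {
  ped <- Pedigree(1:4, c(0, 0, 1, 0), c(0, 0, 2, 0))
  ## u in internal order; look animals up by label
  u <- numeric(4)
  u[pedigreeIds(ped, 1:2)] <- c(2, 4)
  pa <- parentAverage(u, ped)
  expect_equal(pa[pedigreeIds(ped, 3)], 3)
  expect_equal(pa[pedigreeIds(ped, c(1, 2, 4))], c(0, 0, 0))
})

test_that("genomics separates unphenotyped full sibs that BLUP cannot", {
  sim <- smallSim(seed = 9, genotypedFraction = 0.6)
  ped <- sim@ped
  spec <- defaultModelSpecs()$harvestWeight
  vc <- sim@truth$vc$harvestWeight
  qc <- snpQc(sim@geno)
  rel <- buildRelationships(ped, qc$geno)
  ## mask one whole genotyped family
  fam <- paste(ped@sire, ped@dam, sep = "_")
  gi <- pedigreeIds(ped, genotypedAnimals(qc$geno))
  famTab <- table(fam[gi])
  target <- names(famTab)[famTab >= 5][1]
  sibs <- ped@labels[intersect(which(fam == target), gi)]
  masked <- maskPhenotypes(sim@pheno, "harvestWeight", sibs)
  des <- buildDesign(masked, spec, ped)
  fa <- solveMME(des, rel$Ainv, vc)
  fh <- solveMME(des, rel$Hinv, vc, method = "ssGBLUP")
  si <- pedigreeIds(ped, sibs)
  ## pedigree BLUP: all masked sibs collapse to the parent average
  expect_lt(max(abs(ebv(fa)[si] - parentAverage(ebv(fa), ped)[si])), 1e-6)
  ## ssGBLUP: genotypes spread them out
  expect_gt(sd(ebv(fh)[si]), 1e-3)
})

test_that("the selection index averages standardized breeding values", {
  e1 <- c(1, 2, 3, 4)
  expect_equal(selectionIndex(e1, e1), scale(e1)[, 1])
  set.seed(3)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(selectionIndex(a, b), (scale(a)[, 1] + scale(b)[, 1]) / 2)
  ## the candidate best in both traits ranks first
  a2 <- c(5, 1, 2); b2 <- c(9, 3, 1)
  expect_equal(which.max(selectionIndex(a2, b2)), 1L)
  expect_error(selectionIndex(rep(1, 3), 1:3), "zero variance")
})
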