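test_that("QC removes monomorphic, low-MAF and low-call-rate SNPs", {
  map <- toyMap(5)
  d <- rbind(a = c(2, 2, 0, 1, NA), b = c(2, 0, 1, 1, NA),
             c = c(2, 2, 2, 0, NA), d = c(2, 0, 1, 2, 1))
  g <- GenotypeData(d, map)
  qc <- snpQc(g, animalCallMin = 0)
  ## SNP 1 monomorphic, SNP 5 call rate 0.25
  expect_equal(ncol(dosages(qc$geno)), 3L)
  expect_false(anyNA(dosages(qc$geno)))
  expect_equal(qc$report$n_removed[qc$report$filter == "monomorphic"], 1L)

  ## MAF exactly at the threshold is retained (strictly "lower than")
  d2 <- hweDosages(100, rep(0.5, 3))
  d2[, 2] <- c(rep(1, 10), rep(0, 90))          # maf exactly 0.05
  d2[, 3] <- c(rep(1, 8), rep(0, 92))           # maf 0.04 -> removed
  qc2 <- snpQc(GenotypeData(d2, toyMap(3)))
  expect_true("s2" %in% names(snpMap(qc2$geno)))
  expect_false("s3" %in% names(snpMap(qc2$geno)))

  ## everything removed is fatal
  mono <- matrix(2, nrow = 4, ncol = 2,
                 dimnames = list(paste0("x", 1:4), NULL))
  expect_error(suppressWarnings(snpQc(GenotypeData(mono, toyMap(2)))),
               "all SNPs")
})

test_that("QC matches a brute-force filter enumeration with planted failures", {
  set.seed(55)
  d <- hweDosages(50, runif(100, 0.02, 0.5))
  d[sample(length(d), 300)] <- NA
  d[1:3, ] <- NA                                 # three animals fail call rate
  g <- GenotypeData(d, toyMap(100))
  qc <- snpQc(g)

  ## independent recount: animal filter first, then per-SNP rules
  keepA <- rowMeans(!is.na(d)) >= 0.9
  dd <- d[keepA, ]
  p <- colMeans(dd, na.rm = TRUE) / 2
  keepS <- colMeans(!is.na(dd)) >= 0.9 &
    pmin(p, 1 - p) >= 0.05 &
    apply(dd, 2, function(v) length(unique(v[!is.na(v)])) > 1)
  expect_equal(genotypedAnimals(qc$geno), rownames(d)[keepA])
  expect_equal(names(snpMap(qc$geno)), paste0("s", which(keepS)))
})

test_that("allele frequencies come from mean dosage over non-missing calls", {
  g <- GenotypeData(rbind(a = c(2, 0), b = c(2, 1), c = c(2, 2)), toyMap(2))
  expect_equal(unname(alleleFrequencies(g)), c(1, 0.5))
  set.seed(9)
  d <- hweDosages(40, runif(30, 0.1, 0.9))
  d[sample(length(d), 100)] <- NA
  g2 <- GenotypeData(d, toyMap(30))
  counts <- apply(d, 2, function(v) sum(v, na.rm = TRUE) /
                    (2 * sum(!is.na(v))))
  expect_equal(unname(alleleFrequencies(g2)), unname(counts))
})

test_that("VanRaden G matches hand evaluation and its invariances", {
  g <- GenotypeData(rbind(a1 = c(2, 2), a2 = c(0, 0)), toyMap(2))
  G <- buildG(g, p = c(0.5, 0.5))
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2))
  ## identical heterozygotes at p = 0.5: centered rows vanish
  h <- GenotypeData(rbind(a1 = c(1, 1), a2 = c(1, 1)), toyMap(2))
  expect_equal(unname(buildG(h, p = c(0.5, 0.5))), matrix(0, 2, 2))
  ## default weights = identity weights
  set.seed(12)
  d <- hweDosages(15, runif(40, 0.2, 0.8))
  gg <- GenotypeData(d, toyMap(40))
  expect_equal(buildG(gg), buildG(gg, weights = rep(1, 40)))
  ## column order invariance
  sh <- sample(40)
  gswap <- GenotypeData(d[, sh], toyMap(40)[sh, ])
  expect_equal(buildG(gswap), buildG(gg), tolerance = 1e-12)
  ## monomorphic denominator
  expect_error(buildG(gg, p = rep(0, 40)), "denominator")
})

test_that("blending follows (1-b) G + b A22 and preserves definiteness", {
  G <- matrix(c(2, -2, -2, 2), 2)
  expect_equal(blendG(G, diag(2), 0), G)
  expect_equal(blendG(diag(2), diag(2), 0.7), diag(2))
  expect_equal(blendG(G, diag(2), 0.05),
               matrix(c(1.95, -1.9, -1.9, 1.95), 2))
  expect_error(blendG(G, diag(2), 1), "beta")
  expect_error(blendG(G, diag(3), 0.05), "conformable")
  ## blended matrix admits a Cholesky factor
  expect_silent(chol(blendG(G, diag(2), 0.05)))
})

test_that("H-inverse reduces to A-inverse in the degenerate cases", {
  set.seed(21)
  ped <- randomPedigree(40)
  Ainv <- buildAInverse(ped)
  expect_identical(buildHInverse(Ainv, NULL, NULL, integer(0)), Ainv)
  gi <- sample(40, 8)
  A22 <- extractA22(ped, gi)
  expect_equal(as.matrix(buildHInverse(Ainv, A22, A22, gi)),
               as.matrix(Ainv), tolerance = 1e-10)
})

test_that("H-inverse equals the inverse of the textbook H", {
  set.seed(31)
  ped <- Pedigree(1:10, c(0, 0, 0, 0, 1, 1, 3, 5, 7, 7),
                  c(0, 0, 0, 0, 2, 4, 4, 6, 8, 8))
  A <- tabularA(ped)
  gi <- c(5, 6, 9, 10)
  A22 <- extractA22(ped, gi)
  Gb <- A22 + diag(0.15, 4)
  Hinv <- as.matrix(buildHInverse(buildAInverse(ped), A22, Gb, gi))
  ## assemble H directly and invert
  ngi <- setdiff(1:10, gi)
  A12 <- A[ngi, gi]
  A22i <- solve(A22)
  H <- A
  H[gi, gi] <- Gb
  H[ngi, gi] <- A12 %*% A22i %*% Gb
  H[gi, ngi] <- t(H[ngi, gi])
  H[ngi, ngi] <- A[ngi, ngi] - A12 %*% A22i %*% t(A12) +
    A12 %*% A22i %*% Gb %*% A22i %*% t(A12)
  expect_lt(max(abs(Hinv - solve(H))), 1e-8)
  ## singular genomic matrix advises blending
  expect_error(buildHInverse(buildAInverse(ped), A22,
                             matrix(1, 4, 4), gi), "blend")
})

test_that("mean diagonal of G approaches 1 under Hardy-Weinberg", {
  set.seed(61)
  p <- runif(5000, 0.05, 0.95)
  g <- GenotypeData(hweDosages(40, p),
                    toyMap(5000, spacingBp = 1e4))
  G <- buildG(g, p = p)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("genotype readers parse the dosage and PLINK dialects", {
  d <- rbind(a1 = c(0, 1, 2), a2 = c(2, NA, 0))
  colnames(d) <- c("s1", "s2", "s3")
  dosF <- tempfile(); mapF <- tempfile(fileext = ".csv")
  write.table(data.frame(animal = rownames(d), d), dosF,
              row.names = FALSE, quote = FALSE, sep = "\t")
  write.csv(toyMap(3), mapF, row.names = FALSE)
  g <- readGenotypes(dosF, mapF)
  expect_equal(unname(dosages(g)), unname(d))

  rawF <- tempfile(fileext = ".raw"); pmapF <- tempfile(fileext = ".map")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE s1_A s2_G",
               "f a1 0 0 1 -9 0 2", "f a2 0 0 2 -9 1 NA"), rawF)
  writeLines(c("1 s1 0 1000", "1 s2 0 2000"), pmapF)
  gp <- readPlinkRaw(rawF, pmapF)
  expect_equal(dim(dosages(gp)), c(2L, 2L))
  expect_equal(unname(dosages(gp)[, 1]), c(0, 1))
  expect_true(is.na(dosages(gp)["a2", "s2"]))
})
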