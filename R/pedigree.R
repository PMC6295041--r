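#' Construct a Pedigree from animal/sire/dam vectors
#'
#' Identifiers may be arbitrary (character or numeric); `0`, `"0"` and `NA`
#' denote an unknown parent. Rows are topologically sorted so that parents
#' precede offspring and animals are renumbered to dense internal ids
#' `1..n`; the original identifiers are kept as labels.
#'
#' @param animal,sire,dam vectors of identifiers, one entry per animal.
#' @param yearClass optional integer year-class (generation) labels.
#' @return A [Pedigree-class] object.
#' @examples
#' ped <- Pedigree(c("s", "d", "o"), c(0, 0, "s"), c(0, 0, "d"))
#' @export
Pedigree <- function(animal, sire, dam, yearClass = NULL) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  n <- length(animal)
  if (length(sire) != n || length(dam) != n)
    stop("animal, sire and dam must have equal length")
  if (anyDuplicated(animal))
    stop("duplicated animal id: ", animal[duplicated(animal)][1])
  unknown <- function(x) is.na(x) | x == "0" | x == ""
  sire[unknown(sire)] <- NA
  dam[unknown(dam)] <- NA
  bad <- setdiff(c(sire, dam), c(animal, NA))
  if (length(bad) > 0)
    stop("parent id not found in pedigree: ", bad[1])

  ## Kahn topological sort over parent -> offspring edges
  idx <- seq_len(n)
  names(idx) <- animal
  sIdx <- unname(idx[sire])
  dIdx <- unname(idx[dam])
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in idx) {
    for (p in c(sIdx[i], dIdx[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue) > 0) {
    i <- queue[1]
    queue <- queue[-1]
    ord <- c(ord, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) != n)
    stop("pedigree cycle detected involving animal: ",
         animal[which(indeg > 0L)][1])

  newId <- integer(n)
  newId[ord] <- seq_len(n)
  toNew <- function(p) ifelse(is.na(p), 0L, newId[p])
  yc <- if (is.null(yearClass)) rep(NA_integer_, n) else as.integer(yearClass)
  new("Pedigree",
      sire = toNew(sIdx)[ord], dam = toNew(dIdx)[ord],
      labels = animal[ord], yearClass = yc[ord])
}

#' Read a pedigree file
#'
#' Reads a comma- or whitespace-delimited file with columns
#' `animal, sire, dam[, year_class]` (`0` = unknown parent), renumbers and
#' sorts it (see [Pedigree()]).
#'
#' @param path file path.
#' @param header logical; does the file have a header line?
#' @return A [Pedigree-class] object.
#' @export
readPedigree <- function(path, header = TRUE) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = header, sep = sep,
                          colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 3) stop("pedigree file needs at least 3 columns")
  yc <- if (ncol(df) >= 4) suppressWarnings(as.integer(df[[4]])) else NULL
  Pedigree(df[[1]], df[[2]], df[[3]], yearClass = yc)
}

#' Write a renumbered pedigree plus its id map
#'
#' @param ped a [Pedigree-class].
#' @param path output CSV path; the id map (original label to internal id)
#'   is written next to it with suffix `.idmap.csv`.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(ped, path) {
  df <- data.frame(animal = seq_along(ped@sire), sire = ped@sire,
                   dam = ped@dam, year_class = ped@yearClass)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  map <- data.frame(label = ped@labels, id = seq_along(ped@labels))
  utils::write.csv(map, paste0(tools::file_path_sans_ext(path), ".idmap.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Number of animals in a pedigree
#' @param ped a [Pedigree-class].
#' @export
nAnimals <- function(ped) length(ped@sire)

#' Map original animal labels to internal pedigree ids
#' @param ped a [Pedigree-class].
#' @param labels character vector of original identifiers.
#' @return integer internal ids; errors if any label is unknown.
#' @export
pedigreeIds <- function(ped, labels) {
  i <- match(as.character(labels), ped@labels)
  if (anyNA(i))
    stop("animal not in pedigree: ", as.character(labels)[is.na(i)][1])
  i
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes `F` for every animal without forming the dense relationship
#' matrix, so it scales to full pedigrees. Unknown parents are unrelated,
#' non-inbred founders.
#'
#' @param ped a [Pedigree-class].
#' @return numeric vector of inbreeding coefficients, one per animal.
#' @export
computeInbreeding <- function(ped) {
  .ml_inbreeding(ped@sire, ped@dam)
}

#' Dense numerator relationship matrix by the tabular method
#'
#' Test-scale oracle for the sparse machinery: `a_ii = 1 + 0.5 a_{s,d}`,
#' `a_ij = 0.5(a_{j,s} + a_{j,d})`.
#'
#' @param ped a [Pedigree-class].
#' @param maxN refuse to build matrices larger than this (dense storage
#'   guard).
#' @return dense `n x n` matrix `A`.
#' @export
tabularA <- function(ped, maxN = 6000) {
  n <- nAnimals(ped)
  if (n > maxN)
    stop("pedigree too large for dense tabular A (n = ", n,
         " > maxN = ", maxN, ")")
  .tabular_a(ped@sire, ped@dam)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: the Mendelian-sampling variance of
#' animal `i` is `d_i = 0.5 - 0.25 (F_s + F_d)` (with the unknown-parent
#' convention `F = -1`), and each trio contributes `1/d_i` blocks to the
#' sparse triplets.
#'
#' @param ped a [Pedigree-class].
#' @param F inbreeding coefficients (computed if missing).
#' @return symmetric sparse matrix (`Matrix::dsCMatrix`).
#' @export
buildAInverse <- function(ped, F = computeInbreeding(ped)) {
  n <- nAnimals(ped)
  s <- ped@sire
  d <- ped@dam
  Fpar <- function(p) ifelse(p == 0L, -1, F[pmax(p, 1L)])
  di <- 0.5 - 0.25 * (Fpar(s) + Fpar(d))
  a <- 1 / di
  i <- seq_len(n)
  both <- s > 0 & d > 0
  ii <- c(i, i[s > 0], i[d > 0], s[both], s[s > 0], d[d > 0])
  jj <- c(i, s[s > 0], d[d > 0], d[both], s[s > 0], d[d > 0])
  ## the sire-dam cross term appears twice in A-inverse; stored once in the
  ## symmetric triangle unless sire == dam, where both land on the diagonal
  xx <- c(a, -0.5 * a[s > 0], -0.5 * a[d > 0],
          ifelse(s[both] == d[both], 0.5, 0.25) * a[both],
          0.25 * a[s > 0], 0.25 * a[d > 0])
  ## keep lower triangle (row >= col); off-diagonal parent-offspring and
  ## sire-dam terms must land once in the triangle
  swap <- ii < jj
  tmp <- ii[swap]; ii[swap] <- jj[swap]; jj[swap] <- tmp
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            symmetric = TRUE)
  M
}

#' Pedigree relationship matrix among genotyped animals (A22)
#'
#' Extracts the genotyped-animal block of `A` without forming the full dense
#' matrix: the pedigree is pruned to the genotyped animals and their
#' ancestors, the tabular matrix is built on that subset, and the block is
#' extracted.
#'
#' @param ped a [Pedigree-class].
#' @param ids internal ids (integer) or labels (character) of genotyped
#'   animals.
#' @param maxN dense guard for the pruned pedigree size.
#' @return dense matrix over `ids`, in the order given.
#' @export
extractA22 <- function(ped, ids, maxN = 6000) {
  if (is.character(ids)) ids <- pedigreeIds(ped, ids)
  ids <- as.integer(ids)
  n <- nAnimals(ped)
  if (any(ids < 1L | ids > n)) stop("unknown animal id in genotyped set")
  keep <- logical(n)
  keep[ids] <- TRUE
  ## ancestral closure: walk from the youngest down
  for (i in rev(seq_len(n))) {
    if (keep[i]) {
      if (ped@sire[i] > 0L) keep[ped@sire[i]] <- TRUE
      if (ped@dam[i] > 0L) keep[ped@dam[i]] <- TRUE
    }
  }
  sub <- which(keep)
  newId <- integer(n)
  newId[sub] <- seq_along(sub)
  remap <- function(p) ifelse(p == 0L, 0L, newId[pmax(p, 1L)])
  if (length(sub) > maxN)
    stop("pruned pedigree too large for dense A22 (n = ", length(sub), ")")
  A <- .tabular_a(remap(ped@sire[sub]), remap(ped@dam[sub]))
  A[newId[ids], newId[ids], drop = FALSE]
}

#' Generation numbers for a pedigree
#'
#' Year-class labels when available, otherwise the maximal ancestral depth
#' (founders = 0).
#'
#' @param ped a [Pedigree-class].
#' @return integer vector, one generation number per animal.
#' @export
generationNumbers <- function(ped) {
  if (!all(is.na(ped@yearClass))) return(ped@yearClass)
  n <- nAnimals(ped)
  g <- integer(n)
  for (i in seq_len(n)) {
    gs <- if (ped@sire[i] > 0L) g[ped@sire[i]] else -1L
    gd <- if (ped@dam[i] > 0L) g[ped@dam[i]] else -1L
    g[i] <- max(gs, gd) + 1L
  }
  g
}

#' Effective population size from the rate of inbreeding
#'
#' `dF = (F_n - F_{n-1}) / (1 - F_{n-1})` between consecutive generations
#' and `Ne = 1 / (2 dF)`. With more than two generations, `dF` is
#' aggregated as the arithmetic mean of the per-pair values
#' (`method = "mean"`) or taken from the last pair (`method = "last"`).
#'
#' @param meanF numeric vector of per-generation mean inbreeding, oldest
#'   first (e.g. `tapply(computeInbreeding(ped), generationNumbers(ped),
#'   mean)`).
#' @param method `"mean"` or `"last"`.
#' @return list with `Ne` (NA when the aggregated `dF <= 0`), `deltaF`, and
#'   the per-pair `deltaFPerPair`.
#' @export
neFromInbreeding <- function(meanF, method = c("mean", "last")) {
  method <- match.arg(method)
  if (length(meanF) < 2) stop("need at least two generations")
  if (any(meanF[-length(meanF)] >= 1)) stop("F must be < 1")
  num <- diff(meanF)
  den <- 1 - meanF[-length(meanF)]
  dFs <- num / den
  dF <- if (method == "mean") mean(dFs) else dFs[length(dFs)]
  if (dF <= 0) {
    warning("non-positive rate of inbreeding; Ne undefined")
    return(list(Ne = NA_real_, deltaF = dF, deltaFPerPair = dFs))
  }
  list(Ne = 1 / (2 * dF), deltaF = dF, deltaFPerPair = dFs)
}
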