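#' Specify a single-trait animal model
#'
#' The evaluation model is `y = Xb + Zu + Wp + e`: fixed effects `b`
#' (contemporary-group factors and nested covariates), additive genetic
#' effect `u` for every pedigree animal with covariance `A` (pedigree BLUP)
#' or `H` (ssGBLUP), and an independent common-environment effect `p` shared
#' by full sibs from the same spawn (reared in the same tank before
#' communal stocking).
#'
#' @param trait phenotype column name.
#' @param fixed one-sided formula for the fixed effects, e.g.
#'   `~ ysp + sex:age` (harvest weight: year-sex-pond cells plus age nested
#'   within sex) or `~ ysp + yearSex:bodyWeight` (carcass weight with body
#'   weight nested within year-sex).
#' @param spawn column naming the full-sib spawn group, or `NA` for no
#'   common-environment effect.
#' @return A [ModelSpec-class] object.
#' @export
modelSpec <- function(trait, fixed, spawn = "spawn") {
  new("ModelSpec", trait = trait, fixed = stats::as.formula(fixed),
      spawn = as.character(spawn))
}

#' Build the design matrices of the mixed-model equations
#'
#' Records with a missing trait value are excluded from `y` (their animals
#' remain in `u` through the relationship matrix). `X` is reduced to full
#' column rank by QR (reference-level/redundant columns dropped); a warning
#' is issued for factor levels carried by a single record.
#'
#' @param pheno phenotype data.frame with a column `animal` holding
#'   pedigree labels, plus the columns used by `spec`.
#' @param spec a [ModelSpec-class].
#' @param ped the [Pedigree-class].
#' @return list: `y`, dense `X`, sparse `Z` (records x animals), sparse `W`
#'   (records x spawn groups, or NULL), `animals` (internal ids per record),
#'   `spawnLevels`.
#' @export
buildDesign <- function(pheno, spec, ped) {
  ids <- pedigreeIds(ped, pheno$animal)
  y <- pheno[[spec@trait]]
  if (is.null(y)) stop("trait column not found: ", spec@trait)
  keep <- !is.na(y)
  rec <- droplevels(pheno[keep, , drop = FALSE])
  ids <- ids[keep]
  y <- as.numeric(y[keep])

  ## single-level factors (e.g. one contemporary-group cell present) get a
  ## phantom second level so model.matrix can code them; the all-zero dummy
  ## is removed by the rank reduction below
  for (v in all.vars(spec@fixed)) {
    col <- rec[[v]]
    if (is.character(col)) col <- factor(col)
    if (is.factor(col)) {
      col <- droplevels(col)
      if (nlevels(col) < 2)
        col <- factor(col, levels = c(levels(col), ".unused"))
      rec[[v]] <- col
    }
  }
  mf <- stats::model.frame(spec@fixed, data = rec, na.action = stats::na.fail)
  X <- stats::model.matrix(spec@fixed, mf)
  ## single-record factor levels
  for (v in all.vars(spec@fixed)) {
    if (is.factor(rec[[v]]) || is.character(rec[[v]])) {
      tab <- table(rec[[v]])
      if (any(tab == 1))
        warning("factor '", v, "' has singleton level(s): ",
                paste(names(tab)[tab == 1], collapse = ", "))
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]

  n <- nAnimals(ped)
  Z <- Matrix::sparseMatrix(i = seq_along(ids), j = ids, x = 1,
                            dims = c(length(ids), n))
  W <- NULL
  spawnLevels <- character(0)
  if (!is.na(spec@spawn)) {
    sp <- factor(rec[[spec@spawn]])
    if (is.null(rec[[spec@spawn]])) stop("spawn column not found: ", spec@spawn)
    spawnLevels <- levels(sp)
    W <- Matrix::sparseMatrix(i = seq_along(ids), j = as.integer(sp), x = 1,
                              dims = c(length(ids), nlevels(sp)))
  }
  list(y = y, X = X, Z = Z, W = W, animals = ids, spawnLevels = spawnLevels)
}

#' Solve Henderson's mixed-model equations
#'
#' Builds the coefficient matrix with variance ratios
#' `lambda_u = sigma2_e / sigma2_u` on `Kinv` and
#' `lambda_p = sigma2_e / sigma2_p` on the identity for spawn groups, and
#' solves by sparse Cholesky (below `pcgThreshold` equations) or
#' Jacobi-preconditioned conjugate gradients.
#'
#' @param design output of [buildDesign()].
#' @param Kinv sparse relationship inverse: `A^-1` (BLUP) or `H^-1`
#'   (ssGBLUP).
#' @param vc list with `sigma2_u`, `sigma2_p`, `sigma2_e` (strictly positive
#'   `sigma2_e`, `sigma2_u`; `sigma2_p` ignored when the model has no spawn
#'   effect).
#' @param method relationship label stored in the fit (`"BLUP"` or
#'   `"ssGBLUP"`).
#' @param solver `"auto"`, `"direct"` or `"pcg"`.
#' @param tol relative residual tolerance of the normal equations.
#' @param pcgThreshold equation count above which `"auto"` switches to PCG.
#' @param maxIter PCG iteration cap.
#' @return A [MixedModelFit-class].
#' @export
solveMME <- function(design, Kinv, vc, method = "BLUP",
                     solver = c("auto", "direct", "pcg"), tol = 1e-8,
                     pcgThreshold = 5000, maxIter = 5000) {
  solver <- match.arg(solver)
  if (vc$sigma2_e <= 0 || vc$sigma2_u <= 0)
    stop("sigma2_e and sigma2_u must be strictly positive")
  X <- Matrix::Matrix(design$X, sparse = TRUE)
  Z <- design$Z
  W <- design$W
  hasPe <- !is.null(W)
  if (hasPe && (is.null(vc$sigma2_p) || vc$sigma2_p <= 0))
    stop("sigma2_p must be strictly positive for a spawn-group model")
  lambdaU <- vc$sigma2_e / vc$sigma2_u
  T <- if (hasPe) cbind(X, Z, W) else cbind(X, Z)
  C <- Matrix::crossprod(T)
  nx <- ncol(X); nu <- ncol(Z)
  np <- if (hasPe) ncol(W) else 0L
  pen <- if (hasPe) {
    Matrix::bdiag(Matrix::Diagonal(nx, 0), lambdaU * Kinv,
                  Matrix::Diagonal(np, vc$sigma2_e / vc$sigma2_p))
  } else {
    Matrix::bdiag(Matrix::Diagonal(nx, 0), lambdaU * Kinv)
  }
  C <- Matrix::forceSymmetric(C + pen)
  rhs <- as.numeric(Matrix::crossprod(T, design$y))

  neq <- nrow(C)
  useDirect <- solver == "direct" || (solver == "auto" && neq <= pcgThreshold)
  if (useDirect) {
    ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
    sol <- as.numeric(Matrix::solve(ch, rhs))
    iters <- NA_integer_
    solverUsed <- "direct"
  } else {
    pc <- .pcgSolve(C, rhs, tol = tol, maxIter = maxIter)
    sol <- pc$x
    iters <- pc$iterations
    solverUsed <- "pcg"
    if (!pc$converged)
      stop("PCG did not converge after ", maxIter, " iterations; ",
           "residual history tail: ",
           paste(format(utils::tail(pc$history, 5), digits = 3),
                 collapse = ", "))
  }
  rel <- sqrt(sum((as.numeric(C %*% sol) - rhs)^2)) / max(sqrt(sum(rhs^2)), 1e-300)

  b <- sol[seq_len(nx)]
  names(b) <- colnames(design$X)
  u <- sol[nx + seq_len(nu)]
  pe <- if (hasPe) sol[nx + nu + seq_len(np)] else numeric(0)
  if (hasPe) names(pe) <- design$spawnLevels
  new("MixedModelFit", b = b, u = u, pe = pe,
      vc = vc[c("sigma2_u", "sigma2_p", "sigma2_e")], method = method,
      diagnostics = list(solver = solverUsed, relResidual = rel,
                         iterations = iters, nEquations = neq))
}

## Jacobi-preconditioned conjugate gradients on a symmetric sparse system.
.pcgSolve <- function(C, b, tol = 1e-8, maxIter = 5000) {
  dinv <- 1 / Matrix::diag(C)
  x <- numeric(length(b))
  r <- b
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- max(sqrt(sum(b^2)), 1e-300)
  hist <- numeric(0)
  for (it in seq_len(maxIter)) {
    Cp <- as.numeric(C %*% p)
    alpha <- rz / sum(p * Cp)
    x <- x + alpha * p
    r <- r - alpha * Cp
    rel <- sqrt(sum(r^2)) / bnorm
    hist <- c(hist, rel)
    if (rel < tol)
      return(list(x = x, converged = TRUE, iterations = it, history = hist))
    z <- dinv * r
    rzNew <- sum(r * z)
    p <- z + (rzNew / rz) * p
    rz <- rzNew
  }
  list(x = x, converged = FALSE, iterations = maxIter, history = hist)
}

#' Breeding values from a fit
#' @param fit a [MixedModelFit-class].
#' @return numeric vector over all pedigree animals (internal order).
#' @export
ebv <- function(fit) fit@u

#' Fixed-effect estimates from a fit
#' @param fit a [MixedModelFit-class].
#' @export
fixedEffects <- function(fit) fit@b

#' Common-environment effects from a fit
#' @param fit a [MixedModelFit-class].
#' @export
commonEnv <- function(fit) fit@pe

#' Variance components stored in a fit
#' @param fit a [MixedModelFit-class].
#' @export
varComp <- function(fit) fit@vc

#' Phenotypes adjusted for fixed effects
#'
#' `y* = y - X b_full`, with the fixed effects taken from the full-data
#' fit (not from a training fit), as used for scoring validation animals.
#'
#' @param design output of [buildDesign()] on the full data.
#' @param bFull fixed-effect estimates from the full-data fit; its names
#'   must match the columns of `design$X`.
#' @return numeric vector of adjusted phenotypes, one per record.
#' @export
adjustedPhenotypes <- function(design, bFull) {
  X <- design$X
  if (length(bFull) != ncol(X))
    stop("fixed-effect vector does not match the design (",
         length(bFull), " vs ", ncol(X), " columns)")
  as.numeric(design$y - X %*% bFull)
}

#' Parent-average breeding values
#'
#' `PA_i = 0.5 u_sire + 0.5 u_dam`; an unknown parent contributes 0. The
#' deviation `u_i - PA_i` is the estimated Mendelian-sampling term, which is
#' zero for unphenotyped full sibs under pedigree BLUP but not under
#' ssGBLUP with genotypes.
#'
#' @param u breeding values over all pedigree animals (internal order).
#' @param ped the [Pedigree-class].
#' @return numeric vector of parent averages.
#' @export
parentAverage <- function(u, ped) {
  us <- ifelse(ped@sire > 0L, u[pmax(ped@sire, 1L)], 0)
  ud <- ifelse(ped@dam > 0L, u[pmax(ped@dam, 1L)], 0)
  0.5 * us + 0.5 * ud
}

#' Two-trait standardized selection index
#'
#' Each trait's breeding values are z-standardized among the candidates and
#' the index is the mean of the two standardized values, equalizing
#' selection emphasis on the traits.
#'
#' @param ebv1,ebv2 breeding values for the two traits over the same
#'   candidates.
#' @return numeric index, one value per candidate.
#' @export
selectionIndex <- function(ebv1, ebv2) {
  if (length(ebv1) != length(ebv2)) stop("EBV vectors differ in length")
  s1 <- stats::sd(ebv1); s2 <- stats::sd(ebv2)
  if (s1 == 0 || s2 == 0) stop("zero variance in EBV; index undefined")
  ((ebv1 - mean(ebv1)) / s1 + (ebv2 - mean(ebv2)) / s2) / 2
}
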