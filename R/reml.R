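#' EM-REML variance components for the animal model
#'
#' Expectation-maximization REML on Henderson's mixed-model equations:
#' each round solves the lambda-scaled MME at the current components and
#' updates
#' `sigma2_u = (u' Kinv u + tr(Kinv C^uu) sigma2_e) / q_u`,
#' `sigma2_p = (p' p + tr(C^pp) sigma2_e) / q_p`,
#' `sigma2_e = (y'y - sol' rhs) / (n - rank(X))`,
#' where `C^uu`, `C^pp` are blocks of the inverse coefficient matrix.
#' The inverse blocks are obtained through the sparse Cholesky factor, so
#' the method is practical to a few thousand equations.
#'
#' @param design output of [buildDesign()].
#' @param Kinv sparse relationship inverse for `u`.
#' @param init list of starting components (`sigma2_u`, `sigma2_p`,
#'   `sigma2_e`); defaults split the phenotypic variance.
#' @param maxRounds maximum EM rounds.
#' @param tol convergence: maximum relative change of any component.
#' @param boundary components collapsing below `boundary * total` are
#'   pinned there and flagged.
#' @param accelerate apply Aitken extrapolation every few rounds (EM's
#'   per-round updates are monotone but geometrically slow; extrapolation
#'   along the update direction typically cuts rounds by an order of
#'   magnitude). Set `FALSE` for textbook EM steps.
#' @return list: `sigma2_u`, `sigma2_p`, `sigma2_e`, `h2`, `rounds`,
#'   `converged`, `flagged`, `history` (per-round component matrix).
#' @export
emReml <- function(design, Kinv, init = NULL, maxRounds = 500, tol = 1e-6,
                   boundary = 1e-8, accelerate = TRUE) {
  y <- design$y
  X <- Matrix::Matrix(design$X, sparse = TRUE)
  Z <- design$Z
  W <- design$W
  hasPe <- !is.null(W)
  vy <- stats::var(y)
  if (is.null(init)) {
    init <- if (hasPe) {
      list(sigma2_u = vy / 3, sigma2_p = vy / 6, sigma2_e = vy / 2)
    } else {
      list(sigma2_u = vy / 2, sigma2_p = 0, sigma2_e = vy / 2)
    }
  }
  su <- init$sigma2_u; sp <- if (hasPe) init$sigma2_p else 0
  se <- init$sigma2_e
  nx <- ncol(X); nu <- ncol(Z); np <- if (hasPe) ncol(W) else 0L
  nrec <- length(y)
  rankX <- qr(design$X)$rank
  T <- if (hasPe) cbind(X, Z, W) else cbind(X, Z)
  TtT <- Matrix::crossprod(T)
  rhs <- as.numeric(Matrix::crossprod(T, y))
  yy <- sum(y^2)
  Kg <- as(as(Kinv, "generalMatrix"), "TsparseMatrix")
  uRange <- nx + seq_len(nu)
  pRange <- if (hasPe) nx + nu + seq_len(np) else integer(0)
  flagged <- FALSE
  hist <- matrix(NA_real_, nrow = maxRounds, ncol = 3,
                 dimnames = list(NULL, c("sigma2_u", "sigma2_p", "sigma2_e")))
  converged <- FALSE
  round <- 0L
  for (round in seq_len(maxRounds)) {
    pen <- if (hasPe) {
      Matrix::bdiag(Matrix::Diagonal(nx, 0), (se / su) * Kinv,
                    Matrix::Diagonal(np, se / sp))
    } else {
      Matrix::bdiag(Matrix::Diagonal(nx, 0), (se / su) * Kinv)
    }
    C <- Matrix::forceSymmetric(TtT + pen)
    ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE, super = FALSE)
    sol <- as.numeric(Matrix::solve(ch, rhs))
    L <- as(ch, "Matrix")
    tr <- .mme_traces(L@p, L@i, L@x, ch@perm, nx, nu, np,
                      Kg@i, Kg@j, Kg@x)
    u <- sol[uRange]
    suNew <- (as.numeric(Matrix::crossprod(u, Kinv %*% u)) +
                tr$trKC * se) / nu
    if (hasPe) {
      p <- sol[pRange]
      spNew <- (sum(p^2) + tr$trCpp * se) / np
    } else spNew <- 0
    seNew <- (yy - sum(sol * rhs)) / (nrec - rankX)

    total <- suNew + spNew + seNew
    if (suNew < boundary * total) { suNew <- boundary * total; flagged <- TRUE }
    if (hasPe && spNew < boundary * total) {
      spNew <- boundary * total; flagged <- TRUE
    }
    hist[round, ] <- c(suNew, spNew, seNew)
    delta <- max(abs(c(suNew - su, spNew - sp, seNew - se)) /
                   pmax(abs(c(su, sp, se)), 1e-12))
    su <- suNew; sp <- spNew; se <- seNew
    if (delta < tol) { converged <- TRUE; break }
    ## Aitken extrapolation along the EM trajectory every 4th round:
    ## per component, the EM error decays geometrically, so the fixed
    ## point is cur + rate/(1-rate) * step
    if (accelerate && round %% 4 == 0 && round >= 3) {
      d1 <- hist[round, ] - hist[round - 1, ]
      d0 <- hist[round - 1, ] - hist[round - 2, ]
      rate <- ifelse(abs(d0) > 0, d1 / d0, 0)
      ok <- is.finite(rate) & rate > 0 & rate < 0.999
      ext <- hist[round, ]
      ext[ok] <- ext[ok] + rate[ok] / (1 - rate[ok]) * d1[ok]
      if (all(ext[c(1, 3)] > 0) && (!hasPe || ext[2] > 0)) {
        su <- ext[1]; if (hasPe) sp <- ext[2]; se <- ext[3]
      }
    }
  }
  list(sigma2_u = su, sigma2_p = if (hasPe) sp else NA_real_, sigma2_e = se,
       h2 = su / (su + (if (hasPe) sp else 0) + se),
       rounds = round, converged = converged, flagged = flagged,
       history = hist[seq_len(round), , drop = FALSE])
}

#' Restricted log-likelihood of an animal model (test scale)
#'
#' Direct dense evaluation of
#' `-0.5 [ log|V| + log|X'V^-1 X| + y' P y ]` with
#' `V = sigma2_u Z K Z' + sigma2_p W W' + sigma2_e I`. Intended as an
#' independent check of EM fixed points on small data; `K` is obtained by
#' inverting `Kinv` densely.
#'
#' @param design output of [buildDesign()].
#' @param Kinv sparse relationship inverse.
#' @param vc list with `sigma2_u`, `sigma2_p`, `sigma2_e`.
#' @param maxN dense guard on the record count.
#' @return the restricted log-likelihood (constant terms included).
#' @export
remlLogLik <- function(design, Kinv, vc, maxN = 1500) {
  n <- length(design$y)
  if (n > maxN) stop("remlLogLik is a dense test-scale oracle (n > ", maxN, ")")
  K <- solve(as.matrix(Kinv))
  Z <- as.matrix(design$Z)
  X <- design$X
  V <- vc$sigma2_u * Z %*% K %*% t(Z) + diag(vc$sigma2_e, n)
  if (!is.null(design$W)) {
    W <- as.matrix(design$W)
    V <- V + vc$sigma2_p * W %*% t(W)
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       t(design$y) %*% P %*% design$y))
}
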