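## Bayesian Gibbs sampler for the additive + dominance GBLUP: block draws of
## (mu, g_A, g_D) from Henderson's equations and scaled-inverse-chi-square
## draws of the three variance components.

#' Draw one location block of the Gibbs sampler
#'
#' Samples \eqn{g_i \sim N(g_i^*, \sigma_e^2 C_{ii}^{-1})} with
#' \eqn{g_i^* = C_{ii}^{-1}(\gamma_i - C_{i,-i} g_{-i})}, via a Cholesky
#' factorization of the block (no explicit inverse): if \eqn{C_{ii} = R^T R}
#' then \eqn{g_i^* + \sqrt{\sigma_e^2}\, R^{-1} z} has the required
#' distribution for standard normal \eqn{z}.
#'
#' @param Cii positive-definite block of the coefficient matrix (a scalar for
#'   the intercept block).
#' @param rhs the adjusted right-hand side \eqn{\gamma_i - C_{i,-i} g_{-i}}.
#' @param sigma2e current residual variance.
#' @return one draw of the block (numeric vector).
#' @export
sampleLocationBlock <- function(Cii, rhs, sigma2e) {
  Cii <- as.matrix(Cii)
  R <- tryCatch(chol(Cii), error = function(e)
    stop("location block is not positive definite; ",
         "increase the ridge on the relationship matrices", call. = FALSE))
  star <- backsolve(R, forwardsolve(t(R), rhs))
  drop(star + sqrt(sigma2e) * backsolve(R, rnorm(nrow(Cii))))
}

#' Draw a variance component from its scaled inverse chi-square conditional
#'
#' Returns \eqn{(q + S^* v^*) / \chi^2_{n + v^*}} with a fresh chi-square
#' variate, where the quadratic form `q` is \eqn{e^T e} for the residual
#' variance, \eqn{g_A^T K_A^{-1} g_A} for the additive variance and
#' \eqn{g_D^T K_D^{-1} g_D} for the dominance variance.
#'
#' @param q nonnegative quadratic form.
#' @param n number of phenotypic records (degrees of freedom are `n + vStar`).
#' @param sStar,vStar prior scale and degrees of freedom.
#' @param nDraws number of independent draws to return (default 1).
#' @return numeric vector of `nDraws` positive draws.
#' @export
sampleVariance <- function(q, n, sStar, vStar, nDraws = 1L) {
  if (q < 0)
    stop("negative quadratic form: the relationship-matrix inverse has lost symmetry")
  if (q + sStar * vStar <= 0)
    stop("degenerate draw: quadratic form and prior scale are both zero")
  (q + sStar * vStar) / rchisq(nDraws, df = n + vStar)
}

## One chain of the sampler. Assumes the RNG seed has been set by the caller.
##
## The location blocks C_22 = I + lambda_A K_A^-1 and C_33 = I + lambda_D
## K_D^-1 share the eigenvectors of the (fixed) inverse GRMs, so with
## K^-1 = U diag(s) U^T the conditional draw
##   g ~ N(C^-1 rhs, sigma_e^2 C^-1)
## is exactly U [ (U^T rhs) / (1 + lambda s) + sqrt(sigma_e^2) z /
## sqrt(1 + lambda s) ]. Each iteration then costs two n x n
## matrix-vector products per block instead of a fresh Cholesky, and the
## quadratic form g^T K^-1 g is a diagonal sum in the same basis.
## `eigA`/`eigD` carry list(U, s) from one eigendecomposition per fit.
.runChain <- function(y, eigA, eigD, sStar, vStar, nIter, burninFraction,
                      trace = FALSE) {
  n <- length(y)
  sumY <- sum(y)
  UA <- eigA$U; sA <- eigA$s
  UD <- eigD$U; sD <- eigD$s
  ## initial state
  mu <- mean(y)
  gA <- gD <- numeric(n)
  sig2e <- 1
  sig2A <- sig2D <- 0.5
  nBurn <- as.integer(round(burninFraction * nIter))
  nKeep <- nIter - nBurn
  accMu <- 0; accGA <- numeric(n); accGD <- numeric(n)
  accA <- 0; accD <- 0; accE <- 0
  traceMat <- if (trace) matrix(NA_real_, nIter, 3L,
                                dimnames = list(NULL, c("sigma2A", "sigma2D", "sigma2e")))
  for (k in seq_len(nIter)) {
    lambdaA <- sig2e / sig2A
    lambdaD <- sig2e / sig2D
    ## block 1 (intercept): C11 = n
    mu <- rnorm(1L, (sumY - sum(gA) - sum(gD)) / n, sqrt(sig2e / n))
    ## block 2 (additive): C22 = I + KAinv * lambdaA, rhs = y - mu - gD
    dA <- 1 + lambdaA * sA
    vA <- drop(crossprod(UA, y - mu - gD)) / dA + sqrt(sig2e) * rnorm(n) / sqrt(dA)
    gA <- drop(UA %*% vA)
    ## block 3 (dominance): C33 = I + KDinv * lambdaD, rhs = y - mu - gA
    dD <- 1 + lambdaD * sD
    vD <- drop(crossprod(UD, y - mu - gA)) / dD + sqrt(sig2e) * rnorm(n) / sqrt(dD)
    gD <- drop(UD %*% vD)
    ## residuals and variance draws
    e <- y - mu - gA - gD
    sig2e <- (sum(e * e) + sStar * vStar) / rchisq(1L, n + vStar)
    qA <- sum(sA * vA * vA)   # gA^T KAinv gA in the eigenbasis
    qD <- sum(sD * vD * vD)
    sig2A <- (qA + sStar * vStar) / rchisq(1L, n + vStar)
    sig2D <- (qD + sStar * vStar) / rchisq(1L, n + vStar)
    if (!all(is.finite(c(mu, sig2A, sig2D, sig2e))))
      stop(sprintf("sampler state became non-finite at iteration %d", k))
    if (trace) traceMat[k, ] <- c(sig2A, sig2D, sig2e)
    if (k > nBurn) {
      accMu <- accMu + mu
      accGA <- accGA + gA
      accGD <- accGD + gD
      accA <- accA + sig2A
      accD <- accD + sig2D
      accE <- accE + sig2e
    }
  }
  out <- list(mu = accMu / nKeep, gA = accGA / nKeep, gD = accGD / nKeep,
              sigma2A = accA / nKeep, sigma2D = accD / nKeep,
              sigma2e = accE / nKeep, retainedIters = nKeep)
  if (trace) out$trace <- traceMat
  out
}

#' Fit the GBLUP model by Bayesian Gibbs sampling
#'
#' Runs `nChains` independent Gibbs chains. Each chain starts from
#' \eqn{\mu = \bar y}, \eqn{g_A = g_D = 0}, \eqn{\sigma_e^2 = 1},
#' \eqn{\sigma_A^2 = \sigma_D^2 = 0.5}; per iteration it draws the three
#' location blocks in order, the residual vector, and the three variance
#' components from their scaled-inverse-chi-square conditionals with prior
#' scale \eqn{S^* = 0.5V} (V the sample variance of the phenotypes) and
#' \eqn{v^* = 5} by default. The first 90 percent of each chain is
#' discarded, per-chain posterior means are taken over the remainder, and
#' final estimates are the across-chain averages; genomic heritability is
#' computed from the averaged variance components. Chain `m` uses seed
#' `seed + m`, so runs with the same configuration are bitwise reproducible.
#'
#' @param y named numeric vector of training phenotypes, aligned with the
#'   rows of the training GRMs.
#' @param kinship a [KinshipSet-class] whose square blocks cover the
#'   training hybrids.
#' @param config a [GibbsConfig-class].
#' @param trace if `TRUE`, attach per-iteration variance draws of chain 1 as
#'   attribute `"trace"` of the returned fit (diagnostic use).
#' @return a [BGSFit-class].
#' @export
runBGS <- function(y, kinship, config = GibbsConfig(), trace = FALSE) {
  stopifnot(is(kinship, "KinshipSet"), is(config, "GibbsConfig"))
  n <- length(y)
  if (nrow(kinship@KA) != n)
    stop("phenotype length does not match the training kinship dimension")
  if (!is.null(names(y)) && !is.null(rownames(kinship@KA)) &&
      !identical(names(y), rownames(kinship@KA)))
    stop("phenotype names do not match the training kinship row names")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  sStar <- if (is.na(config@sStar)) 0.5 * var(y) else config@sStar
  decomp <- function(Kinv) {
    eg <- eigen(Kinv, symmetric = TRUE)
    list(U = eg$vectors, s = pmax(eg$values, 0))
  }
  eigA <- decomp(kinship@KAinv)
  eigD <- decomp(kinship@KDinv)
  chains <- vector("list", config@nChains)
  for (m in seq_len(config@nChains)) {
    set.seed(config@seed + m)
    chains[[m]] <- tryCatch(
      .runChain(y, eigA, eigD, sStar, config@vStar,
                config@nIter, config@burninFraction,
                trace = trace && m == 1L),
      error = function(e) stop(sprintf("chain %d failed: %s", m,
                                       conditionMessage(e)), call. = FALSE))
  }
  chainDf <- data.frame(
    chain = seq_len(config@nChains),
    mu = vapply(chains, `[[`, numeric(1), "mu"),
    sigma2A = vapply(chains, `[[`, numeric(1), "sigma2A"),
    sigma2D = vapply(chains, `[[`, numeric(1), "sigma2D"),
    sigma2e = vapply(chains, `[[`, numeric(1), "sigma2e"))
  gA <- rowMeans(vapply(chains, `[[`, numeric(n), "gA"))
  gD <- rowMeans(vapply(chains, `[[`, numeric(n), "gD"))
  names(gA) <- names(gD) <- names(y)
  sigma2 <- c(A = mean(chainDf$sigma2A), D = mean(chainDf$sigma2D),
              e = mean(chainDf$sigma2e))
  fit <- new("BGSFit", mu = mean(chainDf$mu), gA = gA, gD = gD,
             sigma2 = sigma2,
             h2 = heritability(sigma2[["A"]], sigma2[["D"]], sigma2[["e"]]),
             chains = chainDf, config = config)
  if (trace) attr(fit, "trace") <- chains[[1L]]$trace
  fit
}
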