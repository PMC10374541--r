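## Henderson's mixed-model equations, genomic heritability, and GEBV
## prediction for the breeding population.

#' Assemble Henderson's equations for the additive + dominance GBLUP
#'
#' Builds the symmetric \eqn{(2n+1)} coefficient matrix with blocks
#' \eqn{C_{11} = n}, \eqn{C_{22} = I + K_A^{-1}\lambda_A},
#' \eqn{C_{33} = I + K_D^{-1}\lambda_D}, unit off-diagonal blocks, and
#' right-hand side \eqn{(1^T y, y, y)}.
#'
#' @param y numeric vector of training phenotypes (length n >= 2).
#' @param KAinv,KDinv inverses of the additive and dominance GRMs (n x n).
#' @param lambdaA,lambdaD positive variance ratios
#'   \eqn{\sigma_e^2/\sigma_A^2} and \eqn{\sigma_e^2/\sigma_D^2}.
#' @return an [MMESystem-class].
#' @export
assembleMME <- function(y, KAinv, KDinv, lambdaA, lambdaD) {
  n <- length(y)
  if (n < 2L) stop("at least two phenotypic records are required")
  if (!all(dim(KAinv) == n) || !all(dim(KDinv) == n))
    stop(sprintf("inverse GRMs must be %d x %d to match the phenotypes", n, n))
  if (lambdaA <= 0 || lambdaD <= 0) stop("lambdaA and lambdaD must be positive")
  ones <- rep(1, n)
  C <- matrix(0, 2 * n + 1, 2 * n + 1)
  C[1, 1] <- n
  C[1, 2:(n + 1)] <- C[2:(n + 1), 1] <- ones
  C[1, (n + 2):(2 * n + 1)] <- C[(n + 2):(2 * n + 1), 1] <- ones
  C[2:(n + 1), 2:(n + 1)] <- KAinv * lambdaA + diag(n)
  C[(n + 2):(2 * n + 1), (n + 2):(2 * n + 1)] <- KDinv * lambdaD + diag(n)
  C[2:(n + 1), (n + 2):(2 * n + 1)] <- diag(n)
  C[(n + 2):(2 * n + 1), 2:(n + 1)] <- diag(n)
  new("MMESystem", coeff = (C + t(C)) / 2, gamma = c(sum(y), y, y),
      lambdaA = as.numeric(lambdaA), lambdaD = as.numeric(lambdaD),
      n = as.integer(n))
}

#' Solve the mixed-model equations
#'
#' Solves \eqn{C (\hat\mu, \hat g_A, \hat g_D)^T = \gamma} through a
#' Cholesky factorization of the symmetric positive-definite coefficient
#' matrix (no explicit inverse is formed).
#'
#' @param system an [MMESystem-class].
#' @return an [MMESolution-class] with the BLUE \eqn{\hat\mu} and the BLUPs
#'   \eqn{\hat g_A}, \eqn{\hat g_D}.
#' @export
solveMME <- function(system) {
  stopifnot(is(system, "MMESystem"))
  n <- system@n
  R <- tryCatch(chol(system@coeff), error = function(e)
    stop("coefficient matrix is singular or indefinite; ",
         "increase the ridge on the relationship matrices", call. = FALSE))
  x <- backsolve(R, forwardsolve(t(R), system@gamma))
  new("MMESolution", mu = x[1], gA = x[2:(n + 1)], gD = x[(n + 2):(2 * n + 1)])
}

#' Genomic heritability from variance components
#'
#' \deqn{h^2 = \frac{\hat\sigma_A^2 + \hat\sigma_D^2}
#'   {\hat\sigma_A^2 + \hat\sigma_D^2 + \hat\sigma_e^2}}
#'
#' @param sigma2A,sigma2D,sigma2e nonnegative variance components with a
#'   positive sum.
#' @return heritability in \[0, 1\] at full double precision (round only for
#'   presentation).
#' @examples
#' heritability(0.306, 0.159, 0.111)  # 0.807 at 3 dp
#' @export
heritability <- function(sigma2A, sigma2D, sigma2e) {
  if (any(c(sigma2A, sigma2D, sigma2e) < 0))
    stop("variance components must be nonnegative")
  tot <- sigma2A + sigma2D + sigma2e
  if (tot <= 0) stop("at least one variance component must be positive")
  (sigma2A + sigma2D) / tot
}

#' Predict GEBVs for the breeding population
#'
#' Carries the training BLUPs to the breeding population through the
#' cross-GRMs,
#' \deqn{\hat g_A^{(bp)} = K_A^{(bp)} K_A^{-1} \hat g_A, \qquad
#'       \hat g_D^{(bp)} = K_D^{(bp)} K_D^{-1} \hat g_D,}
#' and returns \eqn{\hat y^{(bp)} = \hat\mu + \hat g_A^{(bp)} +
#' \hat g_D^{(bp)}}.
#'
#' @param solution an [MMESolution-class] or [BGSFit-class] providing
#'   \eqn{\hat\mu}, \eqn{\hat g_A}, \eqn{\hat g_D}.
#' @param kinship a [KinshipSet-class] with cross blocks for the breeding
#'   population.
#' @param frame the [DiallelFrame-class] the cross-block rows follow.
#' @return a [BreedingPrediction-class].
#' @export
predictBreeding <- function(solution, kinship, frame) {
  stopifnot(is(kinship, "KinshipSet"), is(frame, "DiallelFrame"))
  if (!nrow(kinship@KAcross))
    stop("kinship set has no cross blocks for a breeding population")
  if (nrow(kinship@KAcross) != nHybrids(frame))
    stop("cross blocks do not match the diallel frame")
  mu <- muHat(solution)
  gA <- additiveBLUP(solution)
  gD <- dominanceBLUP(solution)
  gAbp <- drop(kinship@KAcross %*% (kinship@KAinv %*% gA))
  gDbp <- drop(kinship@KDcross %*% (kinship@KDinv %*% gD))
  ids <- hybridIds(frame)
  names(gAbp) <- names(gDbp) <- ids
  gebv <- mu + gAbp + gDbp
  new("BreedingPrediction", frame = frame, mu = mu,
      gAbp = gAbp, gDbp = gDbp, gebv = gebv)
}
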