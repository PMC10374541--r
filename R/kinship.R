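## Genomic relationship matrices and numerically safe inversion.

#' Genomic relationship matrix
#'
#' \eqn{K = X X^T / p} from a standardized marker score matrix with `p`
#' columns. With column-standardized scores the mean of the diagonal is close
#' to 1, the conventional GRM scale.
#'
#' @param X standardized score matrix (individuals in rows).
#' @param p number of markers used as the divisor (default `ncol(X)`).
#' @return symmetric relationship matrix with the row ids of `X`.
#' @export
grm <- function(X, p = ncol(X)) {
  if (p == 0) stop("p must be positive: no markers")
  K <- tcrossprod(X) / p
  (K + t(K)) / 2
}

#' Cross relationship matrix between two populations
#'
#' \eqn{K^{(bp)} = X_{bp} X_{train}^T / p}, the rectangular block relating a
#' breeding population to the training population. Both score matrices must
#' come from one standardization (same markers, same column statistics).
#'
#' @param Xbp score matrix of the breeding population.
#' @param Xtrain score matrix of the training population.
#' @param p divisor (default `ncol(Xtrain)`).
#' @return matrix with one row per breeding individual, one column per
#'   training individual.
#' @export
crossGrm <- function(Xbp, Xtrain, p = ncol(Xtrain)) {
  if (ncol(Xbp) != ncol(Xtrain))
    stop(sprintf("marker count mismatch: %d vs %d columns", ncol(Xbp), ncol(Xtrain)))
  if (p == 0) stop("p must be positive: no markers")
  tcrossprod(Xbp, Xtrain) / p
}

#' Invert a relationship matrix with an adaptive ridge
#'
#' Attempts a Cholesky-based inverse; if the matrix is not positive definite
#' a ridge of `ridgeScale * mean(diag(K))` is added to the diagonal and the
#' attempt is repeated with a doubled ridge, up to `maxTries` times. The
#' dominance GRM of a small hybrid set is frequently rank-deficient, so a
#' recorded, bounded ridge is preferred over silent pseudo-inversion.
#'
#' @param K symmetric matrix.
#' @param ridgeScale starting ridge as a fraction of the mean diagonal
#'   (default `1e-6`).
#' @param maxTries maximum number of doubling attempts (default 10).
#' @return list with `inverse` (symmetrized) and `ridgeUsed` (0 when the
#'   plain Cholesky succeeded).
#' @export
stabilizedInverse <- function(K, ridgeScale = 1e-6, maxTries = 10L) {
  if (nrow(K) != ncol(K)) stop("K must be square")
  if (max(abs(K - t(K))) > 1e-8) stop("K must be symmetric")
  K <- (K + t(K)) / 2
  base <- mean(diag(K))
  if (base <= 0) base <- 1
  ridge <- 0
  for (try in 0:maxTries) {
    Kr <- K
    if (ridge > 0) diag(Kr) <- diag(Kr) + ridge
    R <- tryCatch(chol(Kr), error = function(e) NULL)
    if (!is.null(R)) {
      inv <- chol2inv(R)
      dimnames(inv) <- dimnames(K)
      return(list(inverse = (inv + t(inv)) / 2, ridgeUsed = ridge))
    }
    ridge <- if (ridge == 0) ridgeScale * base else 2 * ridge
  }
  stop(sprintf("matrix still singular after %d ridge attempts (final ridge %g)",
               maxTries, ridge / 2))
}

#' Build the kinship set for training and breeding populations
#'
#' Computes the additive and dominance GRMs over the training rows, the
#' cross-GRMs from the breeding rows to the training rows, and caches
#' stabilized inverses of the square blocks (the Gibbs sampler only rescales
#' them by \eqn{\lambda}, so one inversion suffices).
#'
#' @param coded a [CodedMarkers-class] holding both populations.
#' @param trainingRows ids or indices of the training hybrids.
#' @param breedingRows ids or indices of the breeding hybrids; `NULL` for
#'   none (empty cross blocks).
#' @param ridgeScale passed to [stabilizedInverse()].
#' @return a [KinshipSet-class].
#' @export
makeKinship <- function(coded, trainingRows, breedingRows = NULL,
                        ridgeScale = 1e-6) {
  stopifnot(is(coded, "CodedMarkers"))
  XA <- coded@XA; XD <- coded@XD
  tr <- .resolveRows(XA, trainingRows)
  p <- ncol(XA)
  KA <- grm(XA[tr, , drop = FALSE], p)
  KD <- grm(XD[tr, , drop = FALSE], p)
  if (is.null(breedingRows)) {
    KAc <- KDc <- matrix(numeric(0), 0L, nrow(KA))
  } else {
    bp <- .resolveRows(XA, breedingRows)
    KAc <- crossGrm(XA[bp, , drop = FALSE], XA[tr, , drop = FALSE], p)
    KDc <- crossGrm(XD[bp, , drop = FALSE], XD[tr, , drop = FALSE], p)
  }
  invA <- stabilizedInverse(KA, ridgeScale)
  invD <- stabilizedInverse(KD, ridgeScale)
  new("KinshipSet", KA = KA, KD = KD, KAcross = KAc, KDcross = KDc,
      KAinv = invA$inverse, KDinv = invD$inverse,
      ridge = c(A = invA$ridgeUsed, D = invD$ridgeUsed))
}

#' Export a relationship matrix as CSV
#'
#' Square (or rectangular) matrix written with an id header row and an id
#' first column.
#'
#' @param K relationship matrix with dimnames.
#' @param path output file.
#' @export
writeGRM <- function(K, path) {
  df <- data.frame(id = rownames(K), K, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
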