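#' @import methods
#' @importFrom stats rnorm rchisq runif rbinom var sd cor setNames
#' @importFrom utils combn read.csv read.delim write.csv packageVersion
#' @importFrom utils capture.output
NULL

.PLOIDY_ROLES <- c("parental_inbred", "hybrid")

#' SNP dosage panel for a set of individuals
#'
#' A `MarkerPanel` holds a biallelic SNP dosage matrix (individuals in rows,
#' markers in columns) together with the role of its individuals. Dosages
#' count copies of one allele per locus and take values 0, 1 or 2, with `NA`
#' for missing calls. Panels of inbred parental lines are fully homozygous,
#' so their dosages are restricted to 0, 2 or `NA`.
#'
#' @slot dosages numeric matrix of allele dosages; rownames are individual
#'   ids, colnames are marker ids.
#' @slot ploidyRole `"parental_inbred"` or `"hybrid"`.
#' @slot metadata list of provenance entries, e.g. the quality-control report
#'   attached by [filterMarkers()].
#'
#' @seealso [MarkerPanel()], [filterMarkers()], [imputeMajorAllele()],
#'   [synthesizeHybrids()]
#' @export
setClass("MarkerPanel",
  slots = c(dosages = "matrix", ploidyRole = "character", metadata = "list"),
  prototype = prototype(ploidyRole = "hybrid", metadata = list())
)

setValidity("MarkerPanel", function(object) {
  d <- object@dosages
  msgs <- character()
  if (!is.numeric(d)) {
    msgs <- c(msgs, "'dosages' must be a numeric matrix")
    return(msgs)
  }
  if ((nrow(d) && is.null(rownames(d))) || (ncol(d) && is.null(colnames(d))))
    msgs <- c(msgs, "'dosages' must have individual row names and marker column names")
  if (anyDuplicated(rownames(d)))
    msgs <- c(msgs, "duplicate individual ids")
  if (anyDuplicated(colnames(d)))
    msgs <- c(msgs, "duplicate marker ids")
  if (length(object@ploidyRole) != 1L || !object@ploidyRole %in% .PLOIDY_ROLES)
    msgs <- c(msgs, sprintf("'ploidyRole' must be one of %s",
                            paste(sQuote(.PLOIDY_ROLES), collapse = ", ")))
  v <- d[!is.na(d)]
  allowed <- if (identical(object@ploidyRole, "parental_inbred")) c(0, 2) else c(0, 1, 2)
  if (length(v) && !all(v %in% allowed))
    msgs <- c(msgs, sprintf("dosages must be in {%s} or NA for role '%s'",
                            paste(allowed, collapse = ","), object@ploidyRole))
  if (length(msgs)) msgs else TRUE
})

#' Construct a MarkerPanel
#'
#' @param dosages numeric matrix of dosages in \{0, 1, 2\} (`NA` = missing),
#'   individuals in rows, markers in columns. Row and column names are
#'   required and must be unique.
#' @param ploidyRole `"parental_inbred"` for fully homozygous inbred lines,
#'   `"hybrid"` otherwise.
#' @param onHeterozygote for inbred panels only: `"error"` (default) rejects
#'   heterozygous calls, `"missing"` converts them to `NA` with a warning so
#'   they can be imputed downstream.
#' @return a [MarkerPanel-class] object.
#' @examples
#' d <- matrix(c(0, 2, 2, 0), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("m1", "m2")))
#' MarkerPanel(d, ploidyRole = "parental_inbred")
#' @export
MarkerPanel <- function(dosages, ploidyRole = c("hybrid", "parental_inbred"),
                        onHeterozygote = c("error", "missing")) {
  ploidyRole <- match.arg(ploidyRole)
  onHeterozygote <- match.arg(onHeterozygote)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (ploidyRole == "parental_inbred" && any(dosages == 1, na.rm = TRUE)) {
    if (onHeterozygote == "error")
      stop("heterozygous calls found in a parental_inbred panel; ",
           "inbred parents must be homozygous (use onHeterozygote = \"missing\" ",
           "to convert them to NA and impute)")
    n1 <- sum(dosages == 1, na.rm = TRUE)
    warning(sprintf("%d heterozygous parental call(s) set to missing", n1))
    dosages[dosages == 1] <- NA_real_
  }
  new("MarkerPanel", dosages = dosages, ploidyRole = ploidyRole)
}

#' Half-diallel mating frame
#'
#' All \eqn{N_1 = \binom{N_0}{2}} unordered pairs of \eqn{N_0} parental
#' lines, without selfs or reciprocals. Pairs are stored with index
#' \eqn{i < j} in lexicographic-by-index order.
#'
#' @slot parentIds character vector of the \eqn{N_0} parent ids.
#' @slot pairs integer matrix with \eqn{N_1} rows and columns `i`, `j`.
#' @seealso [halfDiallel()]
#' @export
setClass("DiallelFrame",
  slots = c(parentIds = "character", pairs = "matrix")
)

setValidity("DiallelFrame", function(object) {
  n0 <- length(object@parentIds)
  pr <- object@pairs
  msgs <- character()
  if (anyDuplicated(object@parentIds)) msgs <- c(msgs, "duplicate parent ids")
  if (ncol(pr) != 2L) msgs <- c(msgs, "'pairs' must have two columns")
  else {
    if (nrow(pr) != n0 * (n0 - 1) / 2)
      msgs <- c(msgs, "number of pairs must equal N0*(N0-1)/2")
    if (nrow(pr)) {
      if (any(pr[, 1] >= pr[, 2])) msgs <- c(msgs, "pairs must satisfy i < j (no selfs)")
      if (anyDuplicated(pr)) msgs <- c(msgs, "duplicate pairs")
      if (any(pr < 1) || any(pr > n0)) msgs <- c(msgs, "pair indices out of range")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Standardized marker scores for the GBLUP model
#'
#' Column-standardized additive and dominance score matrices
#' \eqn{X_A} and \eqn{X_D} over a shared marker set. Raw additive scores are
#' \eqn{-1/0/+1} for minor homozygote / heterozygote / major homozygote; raw
#' dominance scores are 1 for the heterozygote and 0 for either homozygote.
#' Each column is centred and scaled by its mean and standard deviation
#' (\eqn{n-1} divisor) over the reference rows, and those `columnStats` are
#' reused for any non-reference rows so that training and breeding
#' populations live on one scale.
#'
#' @slot XA numeric matrix of standardized additive scores.
#' @slot XD numeric matrix of standardized dominance scores (same shape).
#' @slot columnStats list with data frames `additive` and `dominance`, each
#'   holding the per-marker `mean` and `sd` used for standardization.
#' @slot referenceRows character vector of row ids the statistics were
#'   computed on.
#' @seealso [codeMarkers()], [standardizeScores()]
#' @export
setClass("CodedMarkers",
  slots = c(XA = "matrix", XD = "matrix", columnStats = "list",
            referenceRows = "character")
)

setValidity("CodedMarkers", function(object) {
  msgs <- character()
  if (!identical(dim(object@XA), dim(object@XD)))
    msgs <- c(msgs, "XA and XD must have identical shape")
  if (!identical(colnames(object@XA), colnames(object@XD)))
    msgs <- c(msgs, "XA and XD must share marker ids")
  if (!all(c("additive", "dominance") %in% names(object@columnStats)))
    msgs <- c(msgs, "columnStats must contain 'additive' and 'dominance'")
  if (length(msgs)) msgs else TRUE
})

#' Genomic relationship matrices for training and breeding populations
#'
#' Additive and dominance GRMs \eqn{K_A = X_A X_A^T / p} and
#' \eqn{K_D = X_D X_D^T / p} over the training hybrids, the rectangular
#' cross-GRMs relating the breeding population to the training population,
#' and cached stabilized inverses of the square blocks.
#'
#' @slot KA,KD symmetric training-population GRMs.
#' @slot KAcross,KDcross breeding-by-training cross relationship matrices
#'   (zero-row matrices when no breeding population is attached).
#' @slot KAinv,KDinv cached inverses of (possibly ridged) `KA`, `KD`.
#' @slot ridge named numeric, the ridge actually added to the diagonal of
#'   each square block before inversion (0 when none was needed).
#' @seealso [makeKinship()], [grm()], [stabilizedInverse()]
#' @export
setClass("KinshipSet",
  slots = c(KA = "matrix", KD = "matrix",
            KAcross = "matrix", KDcross = "matrix",
            KAinv = "matrix", KDinv = "matrix",
            ridge = "numeric")
)

setValidity("KinshipSet", function(object) {
  msgs <- character()
  n <- nrow(object@KA)
  if (!identical(dim(object@KA), dim(object@KD)))
    msgs <- c(msgs, "KA and KD must have the same dimension")
  for (nm in c("KA", "KD")) {
    K <- slot(object, nm)
    if (nrow(K) != ncol(K)) msgs <- c(msgs, sprintf("%s must be square", nm))
    else if (max(abs(K - t(K))) > 1e-8)
      msgs <- c(msgs, sprintf("%s must be symmetric", nm))
  }
  if (nrow(object@KAcross) && ncol(object@KAcross) != n)
    msgs <- c(msgs, "KAcross must have one column per training individual")
  if (nrow(object@KDcross) && ncol(object@KDcross) != n)
    msgs <- c(msgs, "KDcross must have one column per training individual")
  if (length(msgs)) msgs else TRUE
})

#' Henderson mixed-model equations for the additive + dominance GBLUP
#'
#' The \eqn{(2n+1)\times(2n+1)} symmetric coefficient matrix
#' \deqn{C = \left[\begin{array}{ccc} n & 1^T & 1^T \\ 1 & I + K_A^{-1}\lambda_A & I \\
#'   1 & I & I + K_D^{-1}\lambda_D \end{array}\right]}
#' with right-hand side \eqn{\gamma = (1^T y,\; y,\; y)} and variance ratios
#' \eqn{\lambda_A = \sigma_e^2/\sigma_A^2}, \eqn{\lambda_D = \sigma_e^2/\sigma_D^2}.
#'
#' @slot coeff coefficient matrix.
#' @slot gamma right-hand side vector.
#' @slot lambdaA,lambdaD variance ratios used in the blocks.
#' @slot n number of training records.
#' @seealso [assembleMME()], [solveMME()]
#' @export
setClass("MMESystem",
  slots = c(coeff = "matrix", gamma = "numeric",
            lambdaA = "numeric", lambdaD = "numeric", n = "integer")
)

#' Solution of the mixed-model equations
#'
#' @slot mu the best linear unbiased estimate of the intercept.
#' @slot gA,gD BLUPs of the additive and dominance genotypic values for the
#'   training hybrids.
#' @export
setClass("MMESolution",
  slots = c(mu = "numeric", gA = "numeric", gD = "numeric")
)

#' Configuration of the Bayesian Gibbs sampler
#'
#' @slot nIter iterations per chain (K, default 5000).
#' @slot nChains independent chains (M, default 5); chain m uses seed
#'   `seed + m`.
#' @slot burninFraction fraction of each chain discarded before averaging
#'   (default 0.9: only the final 10 percent of draws is retained).
#' @slot sStar prior scale \eqn{S^*} of the scaled inverse chi-square priors;
#'   `NA` means the default \eqn{0.5V} with \eqn{V} the sample variance of
#'   the phenotypes, computed at run time.
#' @slot vStar prior degrees of freedom \eqn{v^*} (default 5).
#' @slot seed integer base seed for reproducibility.
#' @seealso [GibbsConfig()], [runBGS()]
#' @export
setClass("GibbsConfig",
  slots = c(nIter = "integer", nChains = "integer", burninFraction = "numeric",
            sStar = "numeric", vStar = "numeric", seed = "integer")
)

setValidity("GibbsConfig", function(object) {
  msgs <- character()
  if (object@nIter < 2L) msgs <- c(msgs, "nIter must be at least 2")
  if (object@nChains < 1L) msgs <- c(msgs, "nChains must be at least 1")
  if (object@burninFraction <= 0 || object@burninFraction >= 1)
    msgs <- c(msgs, "burninFraction must be in (0, 1)")
  if (object@nIter - round(object@burninFraction * object@nIter) < 1L)
    msgs <- c(msgs, "at least one post-burn-in iteration is required")
  if (!is.na(object@sStar) && object@sStar < 0)
    msgs <- c(msgs, "sStar must be nonnegative")
  if (object@vStar <= 0) msgs <- c(msgs, "vStar must be positive")
  if (length(msgs)) msgs else TRUE
})

#' @param nIter,nChains,burninFraction,sStar,vStar,seed see the corresponding
#'   slots of [GibbsConfig-class].
#' @return a validated `GibbsConfig`.
#' @examples
#' GibbsConfig(nIter = 2000, nChains = 3, seed = 7)
#' @rdname GibbsConfig-class
#' @export
GibbsConfig <- function(nIter = 5000L, nChains = 5L, burninFraction = 0.9,
                        sStar = NA_real_, vStar = 5, seed = 1L) {
  new("GibbsConfig", nIter = as.integer(nIter), nChains = as.integer(nChains),
      burninFraction = as.numeric(burninFraction), sStar = as.numeric(sStar),
      vStar = as.numeric(vStar), seed = as.integer(seed))
}

#' Fitted GBLUP model from the Bayesian Gibbs sampler
#'
#' Across-chain averages of the posterior means of the intercept, the
#' additive and dominance BLUPs, and the three variance components, plus the
#' genomic heritability derived from them.
#'
#' @slot mu,gA,gD point estimates (posterior means averaged over chains).
#' @slot sigma2 named numeric with elements `A`, `D`, `e`.
#' @slot h2 genomic heritability \eqn{(\sigma_A^2+\sigma_D^2) /
#'   (\sigma_A^2+\sigma_D^2+\sigma_e^2)}.
#' @slot chains data frame of per-chain posterior means (one row per chain).
#' @slot config the [GibbsConfig-class] used.
#' @seealso [runBGS()], [varianceComponents()]
#' @export
setClass("BGSFit",
  slots = c(mu = "numeric", gA = "numeric", gD = "numeric",
            sigma2 = "numeric", h2 = "numeric",
            chains = "data.frame", config = "GibbsConfig")
)

#' GEBV prediction for a breeding population
#'
#' Additive and dominance BLUPs carried from the training population to the
#' breeding population through the cross-GRMs, and the resulting genomic
#' estimated breeding values \eqn{\hat y^{(bp)} = \hat\mu + \hat g_A^{(bp)} +
#' \hat g_D^{(bp)}}.
#'
#' @slot frame the [DiallelFrame-class] the rows follow.
#' @slot mu intercept estimate carried from the fit.
#' @slot gAbp,gDbp,gebv numeric vectors of length \eqn{N_1}, named by hybrid id.
#' @seealso [predictBreeding()]
#' @export
setClass("BreedingPrediction",
  slots = c(frame = "DiallelFrame", mu = "numeric",
            gAbp = "numeric", gDbp = "numeric", gebv = "numeric")
)

setValidity("BreedingPrediction", function(object) {
  n1 <- nrow(object@frame@pairs)
  msgs <- character()
  if (length(object@gebv) != n1 || length(object@gAbp) != n1 ||
      length(object@gDbp) != n1)
    msgs <- c(msgs, "prediction vectors must have one entry per hybrid pair")
  if (n1 && max(abs(object@gebv - (object@mu + object@gAbp + object@gDbp))) > 1e-10)
    msgs <- c(msgs, "gebv must equal mu + gAbp + gDbp")
  if (length(msgs)) msgs else TRUE
})

#' Combining abilities and heterosis over a half diallel
#'
#' Per-hybrid GEBV, specific combining ability (the dominance BLUP),
#' mid-parent heterosis (equal to the SCA under this model) and better-parent
#' heterosis \eqn{SCA_{ij} - |GCA_i - GCA_j|}, together with per-parent
#' general combining abilities derived from the additive BLUPs.
#'
#' @slot frame the underlying [DiallelFrame-class].
#' @slot mu intercept carried from the fit.
#' @slot gebv,sca,mph,bph per-hybrid vectors (length \eqn{N_1}).
#' @slot gca per-parent general combining abilities (length \eqn{N_0}).
#' @slot gbarParent per-parent means of the additive BLUPs.
#' @slot gbarAll overall mean of the additive BLUPs.
#' @seealso [combiningAbility()], [rankHybrids()], [rankParents()]
#' @export
setClass("HybridEvaluation",
  slots = c(frame = "DiallelFrame", mu = "numeric",
            gebv = "numeric", sca = "numeric", mph = "numeric", bph = "numeric",
            gca = "numeric", gbarParent = "numeric", gbarAll = "numeric")
)

setValidity("HybridEvaluation", function(object) {
  n1 <- nrow(object@frame@pairs)
  n0 <- length(object@frame@parentIds)
  msgs <- character()
  if (any(lengths(list(object@gebv, object@sca, object@mph, object@bph)) != n1))
    msgs <- c(msgs, "per-hybrid vectors must have length N1")
  if (length(object@gca) != n0)
    msgs <- c(msgs, "gca must have one entry per parent")
  if (n1 && any(object@bph - object@mph > 1e-10))
    msgs <- c(msgs, "better-parent heterosis cannot exceed mid-parent heterosis")
  if (length(msgs)) msgs else TRUE
})
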