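#' @rdname MarkerPanel-class
#' @export
setMethod("dosages", "MarkerPanel", function(x) x@dosages)

#' @rdname MarkerPanel-class
#' @export
setMethod("individualIds", "MarkerPanel", function(x) rownames(x@dosages))

#' @rdname MarkerPanel-class
#' @export
setMethod("markerIds", "MarkerPanel", function(x) colnames(x@dosages))

#' @rdname MarkerPanel-class
#' @export
setMethod("ploidyRole", "MarkerPanel", function(x) x@ploidyRole)

#' @rdname MarkerPanel-class
#' @export
setMethod("qcReport", "MarkerPanel", function(x) x@metadata$qc)

setMethod("show", "MarkerPanel", function(object) {
  d <- object@dosages
  cat(sprintf("MarkerPanel (%s): %d individuals x %d markers, %.2f%% missing\n",
              object@ploidyRole, nrow(d), ncol(d),
              100 * mean(is.na(d))))
  if (!is.null(object@metadata$qc))
    cat("  QC: ", format(object@metadata$qc), "\n", sep = "")
})

#' @rdname DiallelFrame-class
#' @export
setMethod("parentIds", "DiallelFrame", function(x) x@parentIds)

#' @rdname DiallelFrame-class
#' @export
setMethod("parentPairs", "DiallelFrame", function(x) x@pairs)

#' @rdname DiallelFrame-class
#' @export
setMethod("nParents", "DiallelFrame", function(x) length(x@parentIds))

#' @rdname DiallelFrame-class
#' @export
setMethod("nHybrids", "DiallelFrame", function(x) nrow(x@pairs))

#' @rdname DiallelFrame-class
#' @export
setMethod("hybridIds", "DiallelFrame", function(x) {
  a <- x@parentIds[x@pairs[, 1]]
  b <- x@parentIds[x@pairs[, 2]]
  ## canonical form: parents in sorted order, so a cross and its reciprocal
  ## share one id
  paste0(pmin(a, b), "x", pmax(a, b))
})

setMethod("show", "DiallelFrame", function(object) {
  cat(sprintf("DiallelFrame: %d parents, %d half-diallel hybrid pairs\n",
              nParents(object), nHybrids(object)))
})

#' @rdname CodedMarkers-class
#' @export
setMethod("additiveScores", "CodedMarkers", function(x) x@XA)

#' @rdname CodedMarkers-class
#' @export
setMethod("dominanceScores", "CodedMarkers", function(x) x@XD)

#' @rdname CodedMarkers-class
#' @export
setMethod("columnStats", "CodedMarkers", function(x) x@columnStats)

#' @rdname CodedMarkers-class
#' @export
setMethod("nMarkers", "CodedMarkers", function(x) ncol(x@XA))

setMethod("show", "CodedMarkers", function(object) {
  cat(sprintf("CodedMarkers: %d individuals x %d markers (standardized on %d reference rows)\n",
              nrow(object@XA), ncol(object@XA), length(object@referenceRows)))
})

#' @rdname KinshipSet-class
#' @export
setMethod("kinA", "KinshipSet", function(x) x@KA)

#' @rdname KinshipSet-class
#' @export
setMethod("kinD", "KinshipSet", function(x) x@KD)

#' @rdname KinshipSet-class
#' @export
setMethod("kinACross", "KinshipSet", function(x) x@KAcross)

#' @rdname KinshipSet-class
#' @export
setMethod("kinDCross", "KinshipSet", function(x) x@KDcross)

#' @rdname KinshipSet-class
#' @export
setMethod("ridgeUsed", "KinshipSet", function(x) x@ridge)

setMethod("show", "KinshipSet", function(object) {
  cat(sprintf("KinshipSet: %d training individuals", nrow(object@KA)))
  if (nrow(object@KAcross))
    cat(sprintf(", %d breeding individuals in cross blocks", nrow(object@KAcross)))
  cat(sprintf("\n  mean diag K_A = %.3f, K_D = %.3f; ridge used (A, D) = (%g, %g)\n",
              mean(diag(object@KA)), mean(diag(object@KD)),
              object@ridge[["A"]], object@ridge[["D"]]))
})

#' @rdname MMESolution-class
#' @export
setMethod("muHat", "MMESolution", function(x) x@mu)

#' @rdname MMESolution-class
#' @export
setMethod("additiveBLUP", "MMESolution", function(x) x@gA)

#' @rdname MMESolution-class
#' @export
setMethod("dominanceBLUP", "MMESolution", function(x) x@gD)

setMethod("show", "MMESolution", function(object) {
  cat(sprintf("MMESolution: mu = %.4f, n = %d training BLUPs\n",
              object@mu, length(object@gA)))
})

setMethod("show", "MMESystem", function(object) {
  cat(sprintf("MMESystem: %d x %d, lambda_A = %.4g, lambda_D = %.4g\n",
              nrow(object@coeff), ncol(object@coeff), object@lambdaA, object@lambdaD))
})

#' @rdname BGSFit-class
#' @export
setMethod("varianceComponents", "BGSFit", function(x) {
  c(x@sigma2, h2 = x@h2)
})

#' @rdname BGSFit-class
#' @export
setMethod("muHat", "BGSFit", function(x) x@mu)

#' @rdname BGSFit-class
#' @export
setMethod("additiveBLUP", "BGSFit", function(x) x@gA)

#' @rdname BGSFit-class
#' @export
setMethod("dominanceBLUP", "BGSFit", function(x) x@gD)

setMethod("show", "BGSFit", function(object) {
  cat(sprintf(
    "BGSFit: %d chains x %d iterations (burn-in %.0f%%)\n  mu = %.4f, sigma2_A = %.4f, sigma2_D = %.4f, sigma2_e = %.4f, h2 = %.4f\n",
    object@config@nChains, object@config@nIter,
    100 * object@config@burninFraction, object@mu,
    object@sigma2[["A"]], object@sigma2[["D"]], object@sigma2[["e"]],
    object@h2))
})

#' @rdname BreedingPrediction-class
#' @export
setMethod("gebv", "BreedingPrediction", function(x) x@gebv)

#' @rdname BreedingPrediction-class
#' @export
setMethod("diallelFrame", "BreedingPrediction", function(x) x@frame)

#' @rdname BreedingPrediction-class
#' @export
setMethod("additiveBLUP", "BreedingPrediction", function(x) x@gAbp)

#' @rdname BreedingPrediction-class
#' @export
setMethod("dominanceBLUP", "BreedingPrediction", function(x) x@gDbp)

setMethod("show", "BreedingPrediction", function(object) {
  cat(sprintf("BreedingPrediction: %d hybrids, GEBV range [%.3f, %.3f]\n",
              length(object@gebv), min(object@gebv), max(object@gebv)))
})

#' @rdname HybridEvaluation-class
#' @export
setMethod("gebv", "HybridEvaluation", function(x) x@gebv)

#' @rdname HybridEvaluation-class
#' @export
setMethod("gca", "HybridEvaluation", function(x) x@gca)

#' @rdname HybridEvaluation-class
#' @export
setMethod("sca", "HybridEvaluation", function(x) x@sca)

#' @rdname HybridEvaluation-class
#' @export
setMethod("mph", "HybridEvaluation", function(x) x@mph)

#' @rdname HybridEvaluation-class
#' @export
setMethod("bph", "HybridEvaluation", function(x) x@bph)

#' @rdname HybridEvaluation-class
#' @export
setMethod("diallelFrame", "HybridEvaluation", function(x) x@frame)

setMethod("show", "HybridEvaluation", function(object) {
  cat(sprintf("HybridEvaluation: %d hybrids from %d parents\n",
              nHybrids(object@frame), nParents(object@frame)))
  top <- rankHybrids(object, topK = min(3L, nHybrids(object@frame)))
  cat("  top hybrids by GEBV:\n")
  print(format(top, digits = 4), row.names = FALSE)
})
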