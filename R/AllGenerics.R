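#' @rdname MarkerPanel-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname MarkerPanel-class
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname MarkerPanel-class
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname MarkerPanel-class
#' @export
setGeneric("ploidyRole", function(x) standardGeneric("ploidyRole"))

#' @rdname MarkerPanel-class
#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))

#' @rdname DiallelFrame-class
#' @export
setGeneric("parentIds", function(x) standardGeneric("parentIds"))

#' @rdname DiallelFrame-class
#' @export
setGeneric("parentPairs", function(x) standardGeneric("parentPairs"))

#' @rdname DiallelFrame-class
#' @export
setGeneric("nParents", function(x) standardGeneric("nParents"))

#' @rdname DiallelFrame-class
#' @export
setGeneric("nHybrids", function(x) standardGeneric("nHybrids"))

#' @rdname DiallelFrame-class
#' @export
setGeneric("hybridIds", function(x) standardGeneric("hybridIds"))

#' @rdname CodedMarkers-class
#' @export
setGeneric("additiveScores", function(x) standardGeneric("additiveScores"))

#' @rdname CodedMarkers-class
#' @export
setGeneric("dominanceScores", function(x) standardGeneric("dominanceScores"))

#' @rdname CodedMarkers-class
#' @export
setGeneric("columnStats", function(x) standardGeneric("columnStats"))

#' @rdname CodedMarkers-class
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname KinshipSet-class
#' @export
setGeneric("kinA", function(x) standardGeneric("kinA"))

#' @rdname KinshipSet-class
#' @export
setGeneric("kinD", function(x) standardGeneric("kinD"))

#' @rdname KinshipSet-class
#' @export
setGeneric("kinACross", function(x) standardGeneric("kinACross"))

#' @rdname KinshipSet-class
#' @export
setGeneric("kinDCross", function(x) standardGeneric("kinDCross"))

#' @rdname KinshipSet-class
#' @export
setGeneric("ridgeUsed", function(x) standardGeneric("ridgeUsed"))

#' Extract variance-component estimates
#'
#' @param x a fitted object such as a [BGSFit-class].
#' @return named numeric vector with elements `A`, `D`, `e` (the additive,
#'   dominance and residual variance components) and `h2` (genomic
#'   heritability).
#' @export
setGeneric("varianceComponents", function(x) standardGeneric("varianceComponents"))

#' @rdname MMESolution-class
#' @export
setGeneric("muHat", function(x) standardGeneric("muHat"))

#' @rdname MMESolution-class
#' @export
setGeneric("additiveBLUP", function(x) standardGeneric("additiveBLUP"))

#' @rdname MMESolution-class
#' @export
setGeneric("dominanceBLUP", function(x) standardGeneric("dominanceBLUP"))

#' @rdname BreedingPrediction-class
#' @export
setGeneric("gebv", function(x) standardGeneric("gebv"))

#' @rdname BreedingPrediction-class
#' @export
setGeneric("diallelFrame", function(x) standardGeneric("diallelFrame"))

#' @rdname HybridEvaluation-class
#' @export
setGeneric("gca", function(x) standardGeneric("gca"))

#' @rdname HybridEvaluation-class
#' @export
setGeneric("sca", function(x) standardGeneric("sca"))

#' @rdname HybridEvaluation-class
#' @export
setGeneric("mph", function(x) standardGeneric("mph"))

#' @rdname HybridEvaluation-class
#' @export
setGeneric("bph", function(x) standardGeneric("bph"))

#' Rank hybrids of a half diallel by GEBV
#'
#' @param x a [HybridEvaluation-class].
#' @param topK number of rows to keep (default: all hybrids).
#' @return data frame with columns `hybrid`, `parentI`, `parentJ`, `gebv`,
#'   `sca`, `mph`, `bph`, sorted by GEBV in decreasing order. Ties are broken
#'   by the lexicographic order of the parent pair so the ranking is
#'   deterministic.
#' @export
setGeneric("rankHybrids", function(x, topK = NULL) standardGeneric("rankHybrids"))

#' Rank parental lines by general combining ability
#'
#' @param x a [HybridEvaluation-class].
#' @param topK number of rows to keep (default: all parents).
#' @return data frame with columns `parent`, `gca`, sorted by GCA in
#'   decreasing order, parent id as tiebreak.
#' @export
setGeneric("rankParents", function(x, topK = NULL) standardGeneric("rankParents"))
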