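## GEBV-based combining abilities and heterosis over a half diallel.
##
## Under the additive + dominance GBLUP, the additive BLUP of a hybrid
## decomposes as g_A(ij) = GCA_i + GCA_j and its dominance BLUP is the SCA.
## Mid-parent heterosis then equals the SCA, and better-parent heterosis is
## SCA_ij - |GCA_i - GCA_j|.

#' Specific combining ability from dominance BLUPs
#'
#' Under the model the SCA of hybrid \eqn{P_i \otimes P_j} is its dominance
#' BLUP \eqn{\hat g_D^{(ij)}}; this function attaches hybrid ids.
#'
#' @param gDbp dominance BLUPs for the breeding population (length
#'   \eqn{N_1}).
#' @param frame the matching [DiallelFrame-class].
#' @return named numeric vector of SCAs.
#' @export
scaFromDominance <- function(gDbp, frame) {
  stopifnot(is(frame, "DiallelFrame"), length(gDbp) == nHybrids(frame))
  setNames(as.numeric(gDbp), hybridIds(frame))
}

#' General combining abilities from additive BLUPs
#'
#' Let \eqn{\bar G_A^{(i)}} be the mean additive BLUP over the \eqn{N_0 - 1}
#' hybrids containing parent \eqn{i}, and \eqn{\bar G_A} the mean over all
#' \eqn{N_1} unordered hybrids, each counted once. Then
#' \deqn{\widehat{GCA}_i = \frac{(N_0-1)\,\bar G_A^{(i)}}{N_0-2}
#'   - \frac{N_0\,\bar G_A}{2\,(N_0-2)}.}
#' When the additive BLUPs satisfy \eqn{\hat g_A^{(ij)} = GCA_i + GCA_j}
#' exactly, this mapping recovers the GCA vector exactly; with the overall
#' mean taken over ordered pairs instead, every GCA would be shifted by a
#' constant (rankings unchanged, heterosis not).
#'
#' @param gAbp additive BLUPs for the breeding population (length
#'   \eqn{N_1}).
#' @param frame the matching [DiallelFrame-class]; needs \eqn{N_0 \ge 3}.
#' @return list with `gca` (named, length \eqn{N_0}), `gbarParent`
#'   (\eqn{\bar G_A^{(i)}}) and `gbarAll` (\eqn{\bar G_A}).
#' @export
gcaFromAdditive <- function(gAbp, frame) {
  stopifnot(is(frame, "DiallelFrame"), length(gAbp) == nHybrids(frame))
  n0 <- nParents(frame)
  if (n0 <= 2L)
    stop("GCA requires at least three parents (the estimator divides by N0 - 2)")
  pr <- frame@pairs
  gAbp <- as.numeric(gAbp)
  sums <- numeric(n0)
  for (col in 1:2) {
    agg <- tapply(gAbp, pr[, col], sum)
    idx <- as.integer(names(agg))
    sums[idx] <- sums[idx] + as.numeric(agg)
  }
  gbarParent <- sums / (n0 - 1)
  gbarAll <- mean(gAbp)
  gca <- (n0 - 1) * gbarParent / (n0 - 2) - n0 * gbarAll / (2 * (n0 - 2))
  names(gca) <- names(gbarParent) <- parentIds(frame)
  list(gca = gca, gbarParent = gbarParent, gbarAll = gbarAll)
}

#' Mid-parent heterosis
#'
#' GEBV-based mid-parent heterosis equals the SCA under the additive +
#' dominance model; kept as its own step for table output.
#'
#' @param sca named SCA vector.
#' @return the same vector.
#' @export
midParentHeterosis <- function(sca) sca

#' Better-parent heterosis
#'
#' \deqn{\widehat{BPH}_{ij} = \widehat{SCA}_{ij} -
#'   |\widehat{GCA}_i - \widehat{GCA}_j|,}
#' never exceeding the mid-parent heterosis, with equality exactly when the
#' two parents have equal GCA.
#'
#' @param sca per-hybrid SCA vector (length \eqn{N_1}).
#' @param gca per-parent GCA vector (length \eqn{N_0}).
#' @param frame the matching [DiallelFrame-class].
#' @return named numeric vector of BPHs.
#' @export
betterParentHeterosis <- function(sca, gca, frame) {
  stopifnot(is(frame, "DiallelFrame"),
            length(sca) == nHybrids(frame), length(gca) == nParents(frame))
  pr <- frame@pairs
  setNames(as.numeric(sca) - abs(gca[pr[, 1]] - gca[pr[, 2]]),
           hybridIds(frame))
}

#' Combining abilities and heterosis for a predicted half diallel
#'
#' Derives SCA, GCA, MPH and BPH from a [BreedingPrediction-class] over the
#' full half diallel.
#'
#' @param prediction a [BreedingPrediction-class].
#' @return a [HybridEvaluation-class].
#' @export
combiningAbility <- function(prediction) {
  stopifnot(is(prediction, "BreedingPrediction"))
  frame <- prediction@frame
  scaV <- scaFromDominance(prediction@gDbp, frame)
  g <- gcaFromAdditive(prediction@gAbp, frame)
  mphV <- midParentHeterosis(scaV)
  bphV <- betterParentHeterosis(scaV, g$gca, frame)
  new("HybridEvaluation", frame = frame, mu = prediction@mu,
      gebv = prediction@gebv, sca = scaV, mph = mphV, bph = bphV,
      gca = g$gca, gbarParent = g$gbarParent, gbarAll = g$gbarAll)
}

#' @rdname rankHybrids
#' @export
setMethod("rankHybrids", "HybridEvaluation", function(x, topK = NULL) {
  frame <- x@frame
  pr <- frame@pairs
  pi <- parentIds(frame)[pr[, 1]]
  pj <- parentIds(frame)[pr[, 2]]
  df <- data.frame(hybrid = hybridIds(frame), parentI = pi, parentJ = pj,
                   gebv = as.numeric(x@gebv), sca = as.numeric(x@sca),
                   mph = as.numeric(x@mph), bph = as.numeric(x@bph),
                   stringsAsFactors = FALSE)
  ord <- order(-df$gebv, df$parentI, df$parentJ)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(topK)) {
    if (topK > nrow(df)) stop("topK exceeds the number of hybrids")
    df <- df[seq_len(topK), , drop = FALSE]
  }
  df
})

#' @rdname rankParents
#' @export
setMethod("rankParents", "HybridEvaluation", function(x, topK = NULL) {
  df <- data.frame(parent = parentIds(x@frame), gca = as.numeric(x@gca),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$gca, df$parent), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(topK)) {
    if (topK > nrow(df)) stop("topK exceeds the number of parents")
    df <- df[seq_len(topK), , drop = FALSE]
  }
  df
})
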