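## End-to-end workflow: QC -> hybrid synthesis -> coding -> kinship ->
## Gibbs fit -> half-diallel GEBV prediction -> combining abilities.

#' Evaluate hybrid performance over a half diallel
#'
#' The full genomic-selection workflow for hybrid breeding from inbred
#' parents:
#' \enumerate{
#'   \item marker QC on the parental panel ([filterMarkers()]) and
#'     major-allele imputation ([imputeMajorAllele()]);
#'   \item enumeration of all half-diallel pairs and synthesis of their F1
#'     genotypes ([halfDiallel()], [synthesizeHybrids()]);
#'   \item additive/dominance coding, removal of zero-dominance markers and
#'     standardization, with allele orientation and column statistics taken
#'     over the combined training + breeding hybrids so both populations
#'     share one scale;
#'   \item GRMs and cross-GRMs with cached stabilized inverses
#'     ([makeKinship()]);
#'   \item variance components, intercept and training BLUPs by the Bayesian
#'     Gibbs sampler ([runBGS()]);
#'   \item GEBVs for every candidate hybrid ([predictBreeding()]) and
#'     GEBV-based SCA, GCA, MPH and BPH ([combiningAbility()]).
#' }
#'
#' @param parents a `parental_inbred` [MarkerPanel-class].
#' @param phenotypes named numeric vector of training phenotypes; names are
#'   canonical hybrid ids (`"<A>x<B>"`, parents sorted; see
#'   [canonicalHybridId()]) and every named hybrid must be a pair of
#'   panel parents.
#' @param maxMissingRate,minMAF QC thresholds for [filterMarkers()].
#' @param config a [GibbsConfig-class] for the sampler.
#' @param ridgeScale passed to [makeKinship()].
#' @return list of class `"hybridGS"` with elements `panel` (QC-filtered,
#'   imputed parents), `frame`, `hybrids`, `coded`, `kinship`, `fit`
#'   ([BGSFit-class]), `prediction` ([BreedingPrediction-class]) and
#'   `evaluation` ([HybridEvaluation-class]).
#' @examples
#' parents <- simulateParents(8, 120, seed = 1)
#' frame <- halfDiallel(parents)
#' # phenotypes would normally come from field trials; simulate some here
#' hyb <- synthesizeHybrids(parents, frame)
#' coded <- standardizeScores(dropZeroDominance(codeMarkers(hyb)))
#' kin <- makeKinship(coded, trainingRows = seq_len(nHybrids(frame)))
#' y <- simulatePhenotypes(kin, c(A = 0.4, D = 0.2, e = 0.4), mu = 2, seed = 2)
#' res <- evaluateHybrids(parents, y,
#'                        config = GibbsConfig(nIter = 200, nChains = 1))
#' head(rankHybrids(res$evaluation, topK = 3))
#' @export
evaluateHybrids <- function(parents, phenotypes,
                            maxMissingRate = 0.05, minMAF = 0.05,
                            config = GibbsConfig(), ridgeScale = 1e-6) {
  stopifnot(is(parents, "MarkerPanel"))
  if (!identical(ploidyRole(parents), "parental_inbred"))
    stop("'parents' must be a parental_inbred panel")
  if (is.null(names(phenotypes)))
    stop("phenotypes must be named by hybrid id")
  panel <- filterMarkers(parents, maxMissingRate, minMAF)
  panel <- imputeMajorAllele(panel)
  frame <- halfDiallel(panel)
  hybrids <- synthesizeHybrids(panel, frame)
  ids <- hybridIds(frame)
  trainIds <- canonicalHybridId(names(phenotypes))
  unknown <- setdiff(trainIds, ids)
  if (length(unknown))
    stop("phenotyped hybrid(s) not derivable from the parental panel: ",
         paste(unknown, collapse = ", "))
  names(phenotypes) <- trainIds
  ## coding and standardization over the combined reference set (training
  ## hybrids are rows of the breeding population here)
  raw <- dropZeroDominance(codeMarkers(hybrids))
  coded <- standardizeScores(raw)
  qc <- qcReport(panel)
  if (!is.null(qc)) {
    qc$nRemovedZeroDominance <- length(attr(raw, "removed"))
    qc$nRetained <- qc$nRetained - qc$nRemovedZeroDominance
    panel@metadata$qc <- qc
  }
  kin <- makeKinship(coded, trainingRows = trainIds, breedingRows = ids,
                     ridgeScale = ridgeScale)
  fit <- runBGS(phenotypes, kin, config)
  pred <- predictBreeding(fit, kin, frame)
  evaluation <- combiningAbility(pred)
  structure(list(panel = panel, frame = frame, hybrids = hybrids,
                 coded = coded, kinship = kin, fit = fit,
                 prediction = pred, evaluation = evaluation,
                 config = config),
            class = "hybridGS")
}

#' @export
print.hybridGS <- function(x, ...) {
  cat("Half-diallel genomic-selection run\n")
  qc <- qcReport(x$panel)
  if (!is.null(qc)) cat("  markers: ", format(qc), "\n", sep = "")
  cat(sprintf("  parents: %d, candidate hybrids: %d, training hybrids: %d\n",
              nParents(x$frame), nHybrids(x$frame), length(x$fit@gA)))
  vc <- varianceComponents(x$fit)
  cat(sprintf("  sigma2_A = %.3f, sigma2_D = %.3f, sigma2_e = %.3f, h2 = %.3f, mu = %.3f\n",
              vc[["A"]], vc[["D"]], vc[["e"]], vc[["h2"]], muHat(x$fit)))
  invisible(x)
}
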