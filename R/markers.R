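## Marker QC, half-diallel synthesis, and additive/dominance coding.

.qcReport <- function(nInput, nMissing, nMAF, nZeroDom, thresholds) {
  structure(
    list(nInputMarkers = nInput,
         nRemovedMissing = nMissing,
         nRemovedMAF = nMAF,
         nRemovedZeroDominance = nZeroDom,
         nRetained = nInput - nMissing - nMAF - nZeroDom,
         thresholds = thresholds),
    class = "QCReport")
}

#' @export
format.QCReport <- function(x, ...) {
  sprintf("%d markers in, %d removed by missing rate, %d by MAF, %d by zero dominance column, %d retained",
          x$nInputMarkers, x$nRemovedMissing, x$nRemovedMAF,
          x$nRemovedZeroDominance, x$nRetained)
}

#' @export
print.QCReport <- function(x, ...) {
  cat("QC report:", format(x), "\n")
  cat(sprintf("  thresholds: missing rate < %g, MAF >= %g\n",
              x$thresholds[["maxMissingRate"]], x$thresholds[["minMAF"]]))
  invisible(x)
}

.minorAlleleFreq <- function(dosages) {
  f <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Filter markers by missing rate and minor allele frequency
#'
#' Removes markers whose missing-call rate reaches `maxMissingRate` or whose
#' minor allele frequency (computed from non-missing calls) falls below
#' `minMAF`. The defaults match the common pipeline cutoffs of dropping
#' markers with missing rate >= 0.05 or MAF < 0.05. Markers are tallied by
#' the first failing rule, the missing-rate rule being applied first; the
#' resulting [QCReport] is attached to the returned panel's metadata
#' (see [qcReport()]).
#'
#' @param panel a [MarkerPanel-class].
#' @param maxMissingRate markers with missing rate >= this fraction are
#'   removed.
#' @param minMAF markers with MAF < this fraction are removed.
#' @return the filtered `MarkerPanel` with a QC report in its metadata.
#' @export
filterMarkers <- function(panel, maxMissingRate = 0.05, minMAF = 0.05) {
  stopifnot(is(panel, "MarkerPanel"),
            maxMissingRate >= 0, maxMissingRate <= 1,
            minMAF >= 0, minMAF <= 1)
  d <- panel@dosages
  if (ncol(d) == 0L || nrow(d) == 0L)
    stop("empty marker panel")
  missRate <- colMeans(is.na(d))
  failMiss <- missRate >= maxMissingRate
  maf <- .minorAlleleFreq(d)
  maf[is.nan(maf)] <- 0          # all-missing column: caught by the missing rule
  failMAF <- !failMiss & maf < minMAF
  keep <- !failMiss & !failMAF
  if (!any(keep))
    stop(sprintf("all markers removed by QC (missing rate < %g, MAF >= %g)",
                 maxMissingRate, minMAF))
  report <- .qcReport(ncol(d), sum(failMiss), sum(failMAF), 0L,
                      c(maxMissingRate = maxMissingRate, minMAF = minMAF))
  out <- panel
  out@dosages <- d[, keep, drop = FALSE]
  out@metadata$qc <- report
  validObject(out)
  out
}

#' Impute missing calls with the major-allele homozygote
#'
#' Every missing dosage is replaced by the homozygote of the more frequent
#' allele at that marker (dosage 0 when the counted allele has frequency
#' <= 0.5 over the non-missing calls, dosage 2 otherwise). An exact tie is
#' resolved to dosage 0 with a warning, so imputation is deterministic.
#'
#' @param panel a [MarkerPanel-class]; every marker needs at least one
#'   non-missing call.
#' @return the panel with no missing entries; non-missing calls are untouched.
#' @export
imputeMajorAllele <- function(panel) {
  stopifnot(is(panel, "MarkerPanel"))
  d <- panel@dosages
  if (!anyNA(d)) return(panel)
  nObs <- colSums(!is.na(d))
  if (any(nObs == 0L))
    stop("marker(s) with all calls missing: ",
         paste(colnames(d)[nObs == 0L], collapse = ", "))
  f <- colMeans(d, na.rm = TRUE) / 2   # frequency of the counted allele
  ties <- abs(f - 0.5) < sqrt(.Machine$double.eps) & colSums(is.na(d)) > 0
  if (any(ties))
    warning("major-allele tie (frequency exactly 0.5) at marker(s) ",
            paste(colnames(d)[ties], collapse = ", "),
            "; missing calls imputed as dosage 0")
  fill <- ifelse(f <= 0.5, 0, 2)
  idx <- which(is.na(d))
  d[idx] <- fill[((idx - 1L) %/% nrow(d)) + 1L]
  out <- panel
  out@dosages <- d
  validObject(out)
  out
}

#' Enumerate a half diallel
#'
#' All unordered pairs of parents, without selfs or reciprocals:
#' \eqn{N_1 = \binom{N_0}{2}} hybrid combinations, e.g. 142 parental lines
#' give 10,011 candidate hybrids. Pairs are listed with \eqn{i < j} in
#' lexicographic-by-index order.
#'
#' @param parentIds character vector of at least two distinct parent ids, or
#'   a parental [MarkerPanel-class] whose individual ids are used.
#' @return a [DiallelFrame-class].
#' @examples
#' nHybrids(halfDiallel(paste0("P", 1:24)))  # 276
#' @export
halfDiallel <- function(parentIds) {
  if (is(parentIds, "MarkerPanel")) parentIds <- individualIds(parentIds)
  parentIds <- as.character(parentIds)
  if (length(parentIds) < 2L)
    stop("at least two parents are required")
  if (anyDuplicated(parentIds))
    stop("duplicate parent ids: ",
         paste(unique(parentIds[duplicated(parentIds)]), collapse = ", "))
  pairs <- t(combn(length(parentIds), 2L))
  colnames(pairs) <- c("i", "j")
  new("DiallelFrame", parentIds = parentIds, pairs = pairs)
}

#' Synthesize hybrid genotypes from inbred parents
#'
#' For fully homozygous parents the F1 genotype is determined: identical
#' parental homozygotes give the same homozygote, opposite homozygotes give
#' the heterozygote. Equivalently the hybrid dosage is the mean of the two
#' parental dosages. Rows follow the order of `frame`'s pairs and are named
#' `"<parentI>x<parentJ>"`.
#'
#' @param parents a `parental_inbred` [MarkerPanel-class] with no missing
#'   calls (run [imputeMajorAllele()] first).
#' @param frame a [DiallelFrame-class] over (a subset of) the parents.
#' @return a `hybrid` [MarkerPanel-class] with one row per pair.
#' @export
synthesizeHybrids <- function(parents, frame) {
  stopifnot(is(parents, "MarkerPanel"), is(frame, "DiallelFrame"))
  if (!identical(ploidyRole(parents), "parental_inbred"))
    stop("'parents' must be a parental_inbred panel")
  d <- parents@dosages
  if (anyNA(d))
    stop("parental panel contains missing calls; impute before synthesis")
  idx <- match(frame@parentIds, rownames(d))
  if (anyNA(idx))
    stop("parents missing from the panel: ",
         paste(frame@parentIds[is.na(idx)], collapse = ", "))
  pr <- frame@pairs
  h <- (d[idx[pr[, 1]], , drop = FALSE] + d[idx[pr[, 2]], , drop = FALSE]) / 2
  rownames(h) <- hybridIds(frame)
  out <- new("MarkerPanel", dosages = h, ploidyRole = "hybrid",
             metadata = parents@metadata)
  validObject(out)
  out
}

#' Raw additive and dominance marker scores
#'
#' Codes each SNP as \eqn{-1/0/+1} for the minor-allele homozygote, the
#' heterozygote and the major-allele homozygote (additive score), and as
#' 1 for the heterozygote and 0 for either homozygote (dominance score).
#' Major/minor status is determined from allele frequencies over the
#' reference rows and applied to all rows, so training and breeding
#' populations share one orientation.
#'
#' @param panel a [MarkerPanel-class] with no missing entries.
#' @param referenceRows ids (or indices) of the rows that define allele
#'   frequencies; defaults to all rows.
#' @return list with matrices `additive` and `dominance` of raw scores.
#' @seealso [dropZeroDominance()], [standardizeScores()]
#' @export
codeMarkers <- function(panel, referenceRows = NULL) {
  stopifnot(is(panel, "MarkerPanel"))
  d <- panel@dosages
  if (anyNA(d))
    stop("panel contains missing entries; run imputeMajorAllele() first")
  ref <- .resolveRows(d, referenceRows)
  f <- colMeans(d[ref, , drop = FALSE]) / 2   # frequency of the counted allele
  ## counted allele minor (f <= 0.5): dosage 0 is the major homozygote -> +1
  sign <- ifelse(f <= 0.5, -1, 1)
  XA <- (d - 1) * rep(sign, each = nrow(d))
  XD <- (d == 1) * 1
  dimnames(XA) <- dimnames(XD) <- dimnames(d)
  list(additive = XA, dominance = XD)
}

.resolveRows <- function(m, rows) {
  if (is.null(rows)) return(seq_len(nrow(m)))
  if (is.character(rows)) {
    idx <- match(rows, rownames(m))
    if (anyNA(idx)) stop("unknown row ids: ", paste(rows[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(rows)
}

#' Drop markers whose dominance column is a zero vector
#'
#' A marker with no heterozygote anywhere in the reference rows carries no
#' dominance information and would break standardization; such markers are
#' removed from both the additive and dominance score matrices.
#'
#' @param scores list with `additive` and `dominance` matrices as produced
#'   by [codeMarkers()].
#' @param referenceRows rows over which "all zero" is assessed (default all).
#' @return the filtered score list, with attribute `removed` holding the
#'   dropped marker ids.
#' @export
dropZeroDominance <- function(scores, referenceRows = NULL) {
  stopifnot(is.list(scores), all(c("additive", "dominance") %in% names(scores)))
  XD <- scores$dominance
  ref <- .resolveRows(XD, referenceRows)
  keep <- colSums(XD[ref, , drop = FALSE] != 0) > 0L
  if (!any(keep))
    stop("all markers have zero dominance columns; nothing retained")
  out <- list(additive = scores$additive[, keep, drop = FALSE],
              dominance = XD[, keep, drop = FALSE])
  attr(out, "removed") <- colnames(XD)[!keep]
  out
}

#' Standardize raw marker scores
#'
#' Centres and scales each column of the additive and dominance score
#' matrices by its mean and standard deviation (\eqn{n-1} divisor) over the
#' reference rows. The same column statistics are applied to any remaining
#' rows, which keeps a breeding population on the scale of the training
#' population so that cross-GRMs and square GRMs are commensurate.
#'
#' @param scores list with `additive` and `dominance` raw score matrices.
#' @param referenceRows ids or indices of the rows defining the statistics
#'   (default: all rows).
#' @return a [CodedMarkers-class].
#' @export
standardizeScores <- function(scores, referenceRows = NULL) {
  stopifnot(is.list(scores), all(c("additive", "dominance") %in% names(scores)))
  ref <- .resolveRows(scores$additive, referenceRows)
  std1 <- function(X, what) {
    mu <- colMeans(X[ref, , drop = FALSE])
    s <- apply(X[ref, , drop = FALSE], 2L, sd)
    bad <- s == 0 | is.na(s)
    if (any(bad))
      stop(sprintf("zero-variance %s column(s) over the reference rows: %s (filter before standardizing)",
                   what, paste(colnames(X)[bad], collapse = ", ")))
    list(Z = sweep(sweep(X, 2L, mu, `-`), 2L, s, `/`),
         stats = data.frame(mean = mu, sd = s, row.names = colnames(X)))
  }
  a <- std1(scores$additive, "additive")
  d <- std1(scores$dominance, "dominance")
  new("CodedMarkers", XA = a$Z, XD = d$Z,
      columnStats = list(additive = a$stats, dominance = d$stats),
      referenceRows = as.character(rownames(scores$additive)[ref]))
}
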