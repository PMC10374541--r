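## Synthetic-data generation, the variance-component simulation harness, and
## the k-fold cross-validation protocol.

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      oldSeed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

#' Simulate an inbred parental marker panel
#'
#' Generates fully homozygous biallelic genotypes: per marker a minor allele
#' frequency is drawn uniformly from `mafRange`, and each parent carries the
#' dosage-2 homozygote with probability equal to the major-allele frequency,
#' independently across parents and markers. Markers that come out
#' monomorphic are re-drawn so every column is informative.
#'
#' @param nParents number of inbred lines (\eqn{N_0 \ge 3}).
#' @param nMarkers number of SNP markers.
#' @param mafRange length-2 numeric in (0, 0.5], the MAF spectrum.
#' @param seed integer seed; the same seed reproduces the panel exactly.
#' @return a `parental_inbred` [MarkerPanel-class] with ids `P001, P002, ...`.
#' @export
simulateParents <- function(nParents, nMarkers, mafRange = c(0.05, 0.5),
                            seed = NULL) {
  stopifnot(nParents >= 3, nMarkers >= 1,
            length(mafRange) == 2, mafRange[1] > 0, mafRange[2] <= 0.5,
            mafRange[1] <= mafRange[2])
  .withSeed(seed, {
    q <- runif(nMarkers, mafRange[1], mafRange[2])
    d <- matrix(2 * rbinom(nParents * nMarkers, 1L, rep(1 - q, each = nParents)),
                nrow = nParents)
    mono <- which(apply(d, 2L, function(col) length(unique(col)) == 1L))
    tries <- 0L
    while (length(mono) && tries < 100L) {
      d[, mono] <- 2 * rbinom(nParents * length(mono), 1L,
                              rep(1 - q[mono], each = nParents))
      mono <- mono[apply(d[, mono, drop = FALSE], 2L,
                         function(col) length(unique(col)) == 1L)]
      tries <- tries + 1L
    }
    if (length(mono))
      stop("could not generate polymorphic markers; widen mafRange or add parents")
    dimnames(d) <- list(sprintf("P%03d", seq_len(nParents)),
                        sprintf("M%05d", seq_len(nMarkers)))
    MarkerPanel(d, ploidyRole = "parental_inbred")
  })
}

## PSD-safe draw from N(0, sigma2 * K): eigendecompose once, clip negative
## eigenvalues at zero.
.mvnFactor <- function(K, tol = 1e-8) {
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eg$values) < -tol * max(abs(eg$values), 1))
    stop("relationship matrix is indefinite beyond tolerance")
  eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
}

#' Simulate phenotypes from the additive + dominance GBLUP model
#'
#' Draws \eqn{y = \mu 1 + g_A + g_D + e} with
#' \eqn{g_A \sim N(0, \sigma_A^2 K_A)}, \eqn{g_D \sim N(0, \sigma_D^2 K_D)}
#' and \eqn{e \sim N(0, \sigma_e^2 I)}, using a PSD-safe symmetric square
#' root of each GRM (negative eigenvalues clipped at zero).
#'
#' @param kinship a [KinshipSet-class]; phenotypes are generated for its
#'   training rows.
#' @param vc named numeric with generating variance components `A`, `D`, `e`.
#' @param mu intercept (default 0).
#' @param seed integer seed for reproducibility.
#' @param returnComponents if `TRUE` the genetic and residual components are
#'   attached as attribute `"components"`.
#' @return named numeric vector of phenotypes.
#' @export
simulatePhenotypes <- function(kinship, vc, mu = 0, seed = NULL,
                               returnComponents = FALSE) {
  stopifnot(is(kinship, "KinshipSet"),
            all(c("A", "D", "e") %in% names(vc)), all(vc >= 0))
  n <- nrow(kinship@KA)
  LA <- if (vc[["A"]] > 0) .mvnFactor(kinship@KA)
  LD <- if (vc[["D"]] > 0) .mvnFactor(kinship@KD)
  .withSeed(seed, {
    gA <- if (vc[["A"]] > 0) sqrt(vc[["A"]]) * drop(LA %*% rnorm(n)) else numeric(n)
    gD <- if (vc[["D"]] > 0) sqrt(vc[["D"]]) * drop(LD %*% rnorm(n)) else numeric(n)
    e <- if (vc[["e"]] > 0) rnorm(n, 0, sqrt(vc[["e"]])) else numeric(n)
    y <- mu + gA + gD + e
    names(y) <- rownames(kinship@KA)
    if (returnComponents)
      attr(y, "components") <- list(gA = gA, gD = gD, e = e)
    y
  })
}

#' Variance-component estimator backed by the Gibbs sampler
#'
#' Builds an estimator closure for [runSimulationStudy()] and
#' [crossValidate()]: given phenotypes, a kinship set and a seed it runs
#' [runBGS()] and returns the fit.
#'
#' @param config a [GibbsConfig-class] template; its seed is replaced by the
#'   per-call seed so replicates are independent but reproducible.
#' @return function of `(y, kinship, seed)` returning a [BGSFit-class].
#' @export
bgsEstimator <- function(config = GibbsConfig()) {
  force(config)
  function(y, kinship, seed) {
    cfg <- config
    cfg@seed <- as.integer(seed)
    runBGS(y, kinship, cfg)
  }
}

#' Fixed-variance GBLUP estimator
#'
#' An estimator that skips variance-component estimation: it plugs known
#' variance components into Henderson's equations and solves them once.
#' Useful for fast cross-validation runs and as a deterministic baseline.
#'
#' @param vc named numeric with elements `A`, `D`, `e` (all positive).
#' @return function of `(y, kinship, seed)` returning an [MMESolution-class]
#'   carrying the supplied components as attribute `"sigma2"`.
#' @export
gblupEstimator <- function(vc) {
  stopifnot(all(c("A", "D", "e") %in% names(vc)), all(vc > 0))
  function(y, kinship, seed) {
    sys <- assembleMME(y, kinship@KAinv, kinship@KDinv,
                       lambdaA = vc[["e"]] / vc[["A"]],
                       lambdaD = vc[["e"]] / vc[["D"]])
    sol <- solveMME(sys)
    attr(sol, "sigma2") <- c(A = vc[["A"]], D = vc[["D"]], e = vc[["e"]])
    sol
  }
}

.estimatorSigma2 <- function(fit) {
  if (is(fit, "BGSFit")) fit@sigma2
  else attr(fit, "sigma2")
}

#' Simulation study of variance-component recovery
#'
#' Repeatedly simulates phenotypes from known variance components on a fixed
#' kinship set, re-estimates the components with the supplied estimator, and
#' summarizes per-component bias and dispersion.
#'
#' @param kinship a [KinshipSet-class] (training blocks are used).
#' @param vc generating variance components, named `A`, `D`, `e`.
#' @param mu generating intercept.
#' @param nReplicates number of simulated phenotype sets (default 100, a
#'   desk-scale run; increase for survey-scale studies).
#' @param estimator estimator closure, e.g. [bgsEstimator()].
#' @param seed base seed; replicate r uses `seed + r` for both the
#'   phenotype draw and the estimator.
#' @return list with `estimates` (one row per replicate: `sigma2A`,
#'   `sigma2D`, `sigma2e`) and `summary` (per component: generating value,
#'   mean estimate, bias, relative bias, sd).
#' @export
runSimulationStudy <- function(kinship, vc, mu = 0, nReplicates = 100L,
                               estimator = bgsEstimator(), seed = 1L) {
  stopifnot(nReplicates >= 1)
  est <- matrix(NA_real_, nReplicates, 3L,
                dimnames = list(NULL, c("sigma2A", "sigma2D", "sigma2e")))
  for (r in seq_len(nReplicates)) {
    y <- simulatePhenotypes(kinship, vc, mu, seed = seed + r)
    fit <- estimator(y, kinship, seed + r)
    est[r, ] <- .estimatorSigma2(fit)[c("A", "D", "e")]
  }
  gen <- c(vc[["A"]], vc[["D"]], vc[["e"]])
  mean_ <- colMeans(est)
  summary <- data.frame(
    component = c("A", "D", "e"),
    generating = gen,
    mean = as.numeric(mean_),
    bias = as.numeric(mean_ - gen),
    relBias = as.numeric((mean_ - gen) / gen),
    sd = apply(est, 2L, sd),
    row.names = NULL)
  list(estimates = as.data.frame(est), summary = summary)
}

## Random partition into nFolds clusters of near-equal size (sizes differ by
## at most one).
.foldAssignment <- function(n, nFolds) {
  sample(rep(seq_len(nFolds), length.out = n))
}

#' k-fold cross-validation of GEBV prediction
#'
#' Per repeat, the phenotyped hybrids are partitioned at random into
#' `nFolds` exclusive clusters of near-equal size. Each cluster serves once
#' as the test set while the model is fitted on the remaining clusters;
#' marker orientation, standardization and kinship are recomputed from the
#' training rows only within each fold, so no information leaks from the
#' held-out hybrids. GEBVs for the test cluster are obtained through the
#' cross-GRM route and compared with the held-out phenotypes by Pearson
#' correlation. Ten folds with five repeats give the conventional 50
#' correlation coefficients.
#'
#' @param panel a `hybrid` [MarkerPanel-class] of the phenotyped hybrids
#'   (no missing calls).
#' @param y named numeric phenotypes matching `panel`'s individuals.
#' @param nFolds,nRepeats folds per repeat and number of repeats.
#' @param seed base seed (repeat r shuffles with `seed + r`).
#' @param estimator estimator closure, e.g. [bgsEstimator()] or
#'   [gblupEstimator()].
#' @param ridgeScale passed to [makeKinship()].
#' @return object of class `CVResult`: list with `correlations`
#'   (length `nFolds * nRepeats`; `NA` where a test fold had zero
#'   phenotypic variance), `meanR`, `sdR`, `nFolds`, `nRepeats`,
#'   `nMissing`.
#' @export
crossValidate <- function(panel, y, nFolds = 10L, nRepeats = 5L, seed = 1L,
                          estimator = bgsEstimator(), ridgeScale = 1e-6) {
  stopifnot(is(panel, "MarkerPanel"), !anyNA(dosages(panel)))
  ids <- individualIds(panel)
  if (is.null(names(y))) stop("phenotypes must be named by hybrid id")
  if (!all(names(y) %in% ids)) stop("phenotype ids missing from the panel")
  panel@dosages <- panel@dosages[names(y), , drop = FALSE]
  n <- length(y)
  if (n < nFolds) stop("fewer observations than folds")
  rs <- numeric(0)
  for (r in seq_len(nRepeats)) {
    folds <- .withSeed(seed + r, .foldAssignment(n, nFolds))
    for (f in seq_len(nFolds)) {
      testIdx <- which(folds == f)
      trainIdx <- which(folds != f)
      coded <- .codeForFold(panel, trainIdx)
      kin <- makeKinship(coded, trainingRows = trainIdx,
                         breedingRows = testIdx, ridgeScale = ridgeScale)
      fit <- estimator(y[trainIdx], kin, seed = seed * 1000L + r * 100L + f)
      gAbp <- drop(kin@KAcross %*% (kin@KAinv %*% additiveBLUP(fit)))
      gDbp <- drop(kin@KDcross %*% (kin@KDinv %*% dominanceBLUP(fit)))
      pred <- muHat(fit) + gAbp + gDbp
      yTest <- y[testIdx]
      if (sd(yTest) == 0) {
        warning(sprintf("repeat %d fold %d: zero phenotypic variance in the test fold; correlation undefined", r, f))
        rs <- c(rs, NA_real_)
      } else {
        rs <- c(rs, cor(pred, yTest))
      }
    }
  }
  structure(list(correlations = rs,
                 meanR = mean(rs, na.rm = TRUE),
                 sdR = sd(rs[!is.na(rs)]),
                 nFolds = as.integer(nFolds), nRepeats = as.integer(nRepeats),
                 nMissing = sum(is.na(rs))),
            class = "CVResult")
}

## Training-only coding for one CV fold: orientation, zero-dominance filter,
## constant-column filter and standardization all from the training rows.
.codeForFold <- function(panel, trainIdx) {
  raw <- codeMarkers(panel, referenceRows = trainIdx)
  raw <- dropZeroDominance(raw, referenceRows = trainIdx)
  sdA <- apply(raw$additive[trainIdx, , drop = FALSE], 2L, sd)
  sdD <- apply(raw$dominance[trainIdx, , drop = FALSE], 2L, sd)
  keep <- sdA > 0 & sdD > 0
  if (!any(keep)) stop("no informative markers in the training fold")
  raw$additive <- raw$additive[, keep, drop = FALSE]
  raw$dominance <- raw$dominance[, keep, drop = FALSE]
  standardizeScores(raw, referenceRows = trainIdx)
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("Cross-validation: %d folds x %d repeats = %d correlations (%d undefined)\n",
              x$nFolds, x$nRepeats, length(x$correlations), x$nMissing))
  cat(sprintf("  mean r = %.4f (sd %.4f)\n", x$meanR, x$sdR))
  invisible(x)
}
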