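# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# 5-marker toy panel: marker m3 has 50% missing calls, m5 has MAF 0.02
# (1 minor allele in 50), the rest pass QC at (0.05, 0.05).
toyQCPanel <- function() {
  n <- 50
  d <- matrix(0, n, 5, dimnames = list(sprintf("H%02d", 1:n),
                                       paste0("m", 1:5)))
  d[, 1] <- rep(c(0, 1, 2, 1, 0), 10)          # common marker
  d[, 2] <- rep(c(2, 2, 0, 1, 1), 10)          # common marker
  d[, 3] <- rep(c(0, NA), 25)                  # 50% missing
  d[, 4] <- rep(c(0, 0, 0, 1, 2), 10)          # common marker
  d[1, 5] <- 1                                 # singleton het: MAF 1/100
  MarkerPanel(d, ploidyRole = "hybrid")
}

# Inbred toy parents for hybrid-synthesis tests.
toyParents <- function() {
  d <- matrix(c(0, 2, 2,
                2, 0, 2,
                0, 0, 2,
                2, 2, 0), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("P", 1:4), paste0("m", 1:3)))
  MarkerPanel(d, ploidyRole = "parental_inbred")
}

# Full synthetic half-diallel dataset: parents -> hybrids -> coded scores ->
# kinship over the given training rows.
makeDiallelData <- function(nParents = 10, nMarkers = 300, seed = 1,
                            trainingRows = NULL, breedingRows = NULL) {
  parents <- simulateParents(nParents, nMarkers, seed = seed)
  frame <- halfDiallel(parents)
  hybrids <- synthesizeHybrids(parents, frame)
  coded <- standardizeScores(dropZeroDominance(codeMarkers(hybrids)))
  if (is.null(trainingRows)) trainingRows <- seq_len(nHybrids(frame))
  kin <- makeKinship(coded, trainingRows = trainingRows,
                     breedingRows = breedingRows)
  list(parents = parents, frame = frame, hybrids = hybrids, coded = coded,
       kin = kin, trainingRows = trainingRows)
}

# Random symmetric positive-definite matrix with unit-scale diagonal.
randomSPD <- function(n, jitter = 0.5) {
  A <- matrix(rnorm(n * (n + 2)), n + 2, n)
  K <- crossprod(A) / (n + 2)
  K + jitter * diag(n)
}

# Independent generalized-least-squares oracle for the mixed model
# y = 1 mu + gA + gD + e with gA ~ N(0, s2A KA), gD ~ N(0, s2D KD),
# e ~ N(0, s2e I): mu is the GLS intercept and the BLUPs are the usual
# conditional means. Deliberately avoids Henderson's equations.
glsOracle <- function(y, KA, KD, s2A, s2D, s2e) {
  n <- length(y)
  V <- s2A * KA + s2D * KD + s2e * diag(n)
  Vinv <- solve(V)
  ones <- rep(1, n)
  mu <- drop((t(ones) %*% Vinv %*% y) / (t(ones) %*% Vinv %*% ones))
  resid <- y - mu
  list(mu = mu,
       gA = drop(s2A * KA %*% Vinv %*% resid),
       gD = drop(s2D * KD %*% Vinv %*% resid))
}
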