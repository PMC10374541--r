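test_that("simulated parental panels are inbred, polymorphic and reproducible", {
  p1 <- simulateParents(12, 400, seed = 101)
  p2 <- simulateParents(12, 400, seed = 101)
  expect_identical(dosages(p1), dosages(p2))
  expect_false(identical(dosages(p1), dosages(simulateParents(12, 400, seed = 102))))
  d <- dosages(p1)
  expect_true(all(d %in% c(0, 2)))
  expect_equal(ploidyRole(p1), "parental_inbred")
  # no monomorphic columns survive
  expect_true(all(apply(d, 2, function(x) length(unique(x))) == 2))
  # empirical MAF spectrum stays in bounds and fills the requested range
  pWide <- simulateParents(40, 5000, mafRange = c(0.1, 0.4), seed = 103)
  maf <- apply(dosages(pWide), 2, function(x) min(mean(x) / 2, 1 - mean(x) / 2))
  expect_true(all(maf > 0 & maf <= 0.5))
  expect_lt(abs(mean(maf) - 0.25), 0.03)  # mean of U(0.1, 0.4) up to sampling noise
  expect_error(simulateParents(2, 10), "nParents")
})

test_that("phenotype simulation honours the generating variance components", {
  dat <- makeDiallelData(nParents = 8, nMarkers = 150, seed = 105)
  kin <- dat$kin
  # all-zero variance: y is exactly the intercept
  y0 <- simulatePhenotypes(kin, c(A = 0, D = 0, e = 0), mu = 3.5, seed = 1)
  expect_equal(unname(y0), rep(3.5, nrow(kinA(kin))))
  expect_named(y0, rownames(kinA(kin)))
  # reproducibility is bitwise
  yA <- simulatePhenotypes(kin, c(A = .4, D = .2, e = .4), mu = 1, seed = 9)
  yB <- simulatePhenotypes(kin, c(A = .4, D = .2, e = .4), mu = 1, seed = 9)
  expect_identical(yA, yB)
  # noise-only model: pooled sample variance approaches sigma2_e
  ys <- unlist(lapply(1:40, function(s)
    simulatePhenotypes(kin, c(A = 0, D = 0, e = 0.5), mu = 2, seed = s)))
  expect_equal(var(ys), 0.5, tolerance = 0.05)
  expect_equal(mean(ys), 2, tolerance = 0.05)
  # identity kinship: total variance is the sum of the three components
  n <- 60
  idKin <- new("KinshipSet", KA = diag(n), KD = diag(n),
               KAcross = matrix(numeric(0), 0, n),
               KDcross = matrix(numeric(0), 0, n),
               KAinv = diag(n), KDinv = diag(n), ridge = c(A = 0, D = 0))
  rownames(idKin@KA) <- colnames(idKin@KA) <- paste0("i", 1:n)
  yy <- unlist(lapply(1:50, function(s)
    simulatePhenotypes(idKin, c(A = .3, D = .2, e = .5), seed = 200 + s)))
  expect_equal(var(yy), 1.0, tolerance = 0.08)
  # genetic components are returned on request and sum to y
  yc <- simulatePhenotypes(kin, c(A = .4, D = .2, e = .4), mu = 1, seed = 11,
                           returnComponents = TRUE)
  comp <- attr(yc, "components")
  expect_equal(unname(1 + comp$gA + comp$gD + comp$e), unname(as.numeric(yc)))
})

test_that("the simulation harness reports unbiased results for an oracle estimator", {
  dat <- makeDiallelData(nParents = 6, nMarkers = 100, seed = 107)
  vc <- c(A = 0.306, D = 0.159, e = 0.111)
  oracle <- function(y, kin, seed) {
    sol <- new("MMESolution", mu = 0, gA = numeric(length(y)),
               gD = numeric(length(y)))
    attr(sol, "sigma2") <- vc
    sol
  }
  res <- runSimulationStudy(dat$kin, vc, nReplicates = 3, estimator = oracle,
                            seed = 2)
  expect_equal(res$summary$bias, rep(0, 3))
  expect_equal(nrow(res$estimates), 3)
  # single replicate reduces to a single estimate row
  res1 <- runSimulationStudy(dat$kin, vc, nReplicates = 1, estimator = oracle,
                             seed = 2)
  expect_equal(nrow(res1$estimates), 1)
})

test_that("fold assignment partitions every individual exactly once with near-equal sizes", {
  for (rep in 1:5) {
    set.seed(rep)
    folds <- diallelGS:::.foldAssignment(119, 10)
    expect_equal(length(folds), 119)
    sizes <- as.numeric(table(factor(folds, levels = 1:10)))
    expect_equal(sum(sizes), 119)
    expect_equal(sort(sizes), c(11, rep(12, 9)))  # nine folds of 12, one of 11
    expect_lte(diff(range(sizes)), 1)
  }
})

test_that("cross-validation yields nFolds x nRepeats correlations, reproducibly", {
  dat <- makeDiallelData(nParents = 8, nMarkers = 120, seed = 109)
  y <- simulatePhenotypes(dat$kin, c(A = .5, D = .2, e = .3), mu = 2,
                          seed = 110)
  est <- gblupEstimator(c(A = .5, D = .2, e = .3))
  cv <- crossValidate(dat$hybrids, y, nFolds = 4, nRepeats = 2, seed = 3,
                      estimator = est)
  expect_s3_class(cv, "CVResult")
  expect_length(cv$correlations, 8)
  expect_equal(cv$nMissing, 0)
  expect_true(all(abs(cv$correlations) <= 1))
  expect_equal(cv$meanR, mean(cv$correlations))
  cv2 <- crossValidate(dat$hybrids, y, nFolds = 4, nRepeats = 2, seed = 3,
                       estimator = est)
  expect_identical(cv$correlations, cv2$correlations)
  # a genetically informative simulation should validate far above chance
  expect_gt(cv$meanR, 0.2)
  expect_error(crossValidate(dat$hybrids, y[1:3], nFolds = 10, seed = 1,
                             estimator = est), "fewer observations")
  expect_error(crossValidate(dat$hybrids, unname(y), estimator = est),
               "named")
})

test_that("the Gibbs estimator plugs into both the harness and cross-validation", {
  dat <- makeDiallelData(nParents = 7, nMarkers = 120, seed = 111)
  y <- simulatePhenotypes(dat$kin, c(A = .4, D = .2, e = .4), mu = 1,
                          seed = 112)
  est <- bgsEstimator(GibbsConfig(nIter = 200, nChains = 1))
  fit <- est(y, dat$kin, seed = 4)
  expect_s4_class(fit, "BGSFit")
  expect_equal(fit@config@seed, 4L)
  cv <- crossValidate(dat$hybrids, y, nFolds = 3, nRepeats = 1, seed = 5,
                      estimator = est)
  expect_length(cv$correlations, 3)
})
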