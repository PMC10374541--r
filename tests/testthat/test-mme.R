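test_that("Henderson coefficient matrix has the documented block structure", {
  y <- c(1, 2, 3)
  sys <- assembleMME(y, diag(3), diag(3), lambdaA = 1, lambdaD = 1)
  C <- sys@coeff
  # n = 3, identity K inverses, unit lambdas: diagonal (3, 2, 2, 2, 2, 2, 2)
  expect_equal(diag(C), c(3, 2, 2, 2, 2, 2, 2))
  expect_equal(C[1, 2:7], rep(1, 6))
  expect_equal(C[2:4, 5:7], diag(3))
  expect_equal(C, t(C))
  expect_equal(sys@gamma, c(6, 1, 2, 3, 1, 2, 3))
  expect_error(assembleMME(y, diag(2), diag(3), 1, 1), "match")
  expect_error(assembleMME(y, diag(3), diag(3), 0, 1), "positive")
})

test_that("solveMME solves the system and collapses to the sample mean under heavy shrinkage", {
  set.seed(31)
  n <- 12
  KAinv <- solve(randomSPD(n))
  KDinv <- solve(randomSPD(n))
  y <- rnorm(n, 5)
  sys <- assembleMME(y, KAinv, KDinv, 0.7, 1.3)
  sol <- solveMME(sys)
  x <- c(muHat(sol), additiveBLUP(sol), dominanceBLUP(sol))
  expect_lt(max(abs(sys@coeff %*% x - sys@gamma)), 1e-8 * max(abs(sys@gamma)))

  # lambda -> infinity shrinks both BLUP vectors to zero and mu to ybar
  big <- solveMME(assembleMME(y, KAinv, KDinv, 1e9, 1e9))
  expect_lt(max(abs(additiveBLUP(big))), 1e-6)
  expect_lt(max(abs(dominanceBLUP(big))), 1e-6)
  expect_equal(muHat(big), mean(y), tolerance = 1e-6)
})

test_that("solveMME matches the closed-form GLS mixed-model oracle", {
  set.seed(33)
  for (rep in 1:5) {
    n <- sample(6:15, 1)
    KA <- randomSPD(n); KD <- randomSPD(n)
    s2A <- runif(1, .2, 2); s2D <- runif(1, .2, 2); s2e <- runif(1, .2, 2)
    y <- rnorm(n, 3)
    sol <- solveMME(assembleMME(y, solve(KA), solve(KD),
                                s2e / s2A, s2e / s2D))
    oracle <- glsOracle(y, KA, KD, s2A, s2D, s2e)
    expect_equal(muHat(sol), oracle$mu, tolerance = 1e-6)
    expect_equal(additiveBLUP(sol), oracle$gA, tolerance = 1e-6)
    expect_equal(dominanceBLUP(sol), oracle$gD, tolerance = 1e-6)
  }
})

test_that("solution is invariant to a simultaneous permutation of individuals", {
  set.seed(35)
  n <- 9
  KA <- randomSPD(n); KD <- randomSPD(n)
  y <- rnorm(n)
  sol <- solveMME(assembleMME(y, solve(KA), solve(KD), 0.5, 0.9))
  perm <- sample(n)
  solP <- solveMME(assembleMME(y[perm], solve(KA[perm, perm]),
                               solve(KD[perm, perm]), 0.5, 0.9))
  expect_equal(muHat(solP), muHat(sol), tolerance = 1e-8)
  expect_equal(additiveBLUP(solP), additiveBLUP(sol)[perm], tolerance = 1e-8)
  expect_equal(dominanceBLUP(solP), dominanceBLUP(sol)[perm], tolerance = 1e-8)
})

test_that("genomic heritability is the variance ratio, scale-invariant, guarded at the edges", {
  expect_equal(round(heritability(0.306, 0.159, 0.111), 3), 0.807)
  expect_equal(round(heritability(0.434, 0.420, 1.202), 3), 0.415)
  expect_equal(heritability(0, 0.5, 0), 1)
  expect_equal(heritability(0, 0, 1), 0)
  h <- heritability(0.3, 0.2, 0.5)
  for (c in c(0.01, 7, 1e6))
    expect_equal(heritability(0.3 * c, 0.2 * c, 0.5 * c), h)
  expect_error(heritability(0, 0, 0), "positive")
  expect_error(heritability(-0.1, 0.2, 0.5), "nonnegative")
})

test_that("breeding-population prediction matches the two-step product oracle and is linear", {
  set.seed(37)
  n <- 8
  frame <- halfDiallel(paste0("Q", 1:5))   # 10 breeding hybrids
  n1 <- nHybrids(frame)
  KA <- randomSPD(n); KD <- randomSPD(n)
  KAc <- matrix(rnorm(n1 * n), n1, n) / 4
  KDc <- matrix(rnorm(n1 * n), n1, n) / 4
  kin10 <- new("KinshipSet", KA = KA, KD = KD, KAcross = KAc, KDcross = KDc,
               KAinv = solve(KA), KDinv = solve(KD), ridge = c(A = 0, D = 0))
  sol <- new("MMESolution", mu = 1.5, gA = rnorm(n), gD = rnorm(n))
  pred <- predictBreeding(sol, kin10, frame)
  oracleA <- drop(KAc %*% solve(KA) %*% sol@gA)
  oracleD <- drop(KDc %*% solve(KD) %*% sol@gD)
  expect_equal(unname(additiveBLUP(pred)), oracleA, tolerance = 1e-8)
  expect_equal(unname(gebv(pred)), 1.5 + oracleA + oracleD, tolerance = 1e-8)

  # linearity: doubling the training BLUPs doubles the carried BLUPs
  sol2 <- new("MMESolution", mu = 1.5, gA = 2 * sol@gA, gD = sol@gD)
  pred2 <- predictBreeding(sol2, kin10, frame)
  expect_equal(additiveBLUP(pred2), 2 * additiveBLUP(pred), tolerance = 1e-10)

  # zero cross blocks: every GEBV equals the intercept
  kin0 <- new("KinshipSet", KA = KA, KD = KD,
              KAcross = matrix(0, 10, n), KDcross = matrix(0, 10, n),
              KAinv = solve(KA), KDinv = solve(KD), ridge = c(A = 0, D = 0))
  pred0 <- predictBreeding(sol, kin0, frame)
  expect_equal(unname(gebv(pred0)), rep(1.5, n1))

  # missing cross blocks -> error
  kinNone <- new("KinshipSet", KA = KA, KD = KD,
                 KAcross = matrix(numeric(0), 0, n),
                 KDcross = matrix(numeric(0), 0, n),
                 KAinv = solve(KA), KDinv = solve(KD), ridge = c(A = 0, D = 0))
  expect_error(predictBreeding(sol, kinNone, frame), "no cross blocks")
})

test_that("with breeding set equal to training set the training BLUPs are recovered exactly", {
  # n < N0 keeps both GRMs full rank, so no ridge is involved
  dat <- makeDiallelData(nParents = 20, nMarkers = 500, seed = 41,
                         trainingRows = 1:15, breedingRows = 1:15)
  kin <- dat$kin
  expect_equal(unname(ridgeUsed(kin)), c(0, 0))
  frame15 <- new("DiallelFrame", parentIds = paste0("Z", 1:6),
                 pairs = t(combn(6, 2)))
  sol <- new("MMESolution", mu = 2, gA = rnorm(15), gD = rnorm(15))
  pred <- predictBreeding(sol, kin, frame15)
  expect_equal(unname(additiveBLUP(pred)), sol@gA, tolerance = 1e-8)
  expect_equal(unname(dominanceBLUP(pred)), sol@gD, tolerance = 1e-8)
})
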