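test_that("marker QC removes by missing rate first, then MAF, and reports counts", {
  panel <- toyQCPanel()
  out <- filterMarkers(panel, maxMissingRate = 0.05, minMAF = 0.05)
  expect_identical(markerIds(out), c("m1", "m2", "m4"))
  rep <- qcReport(out)
  expect_equal(rep$nInputMarkers, 5)
  expect_equal(rep$nRemovedMissing, 1)
  expect_equal(rep$nRemovedMAF, 1)
  expect_equal(rep$nRetained, 3)
  expect_equal(rep$nInputMarkers,
               rep$nRetained + rep$nRemovedMissing + rep$nRemovedMAF +
                 rep$nRemovedZeroDominance)

  # all-pass case: panel returned with identical dosages, zero removals
  clean <- filterMarkers(out, 0.05, 0.05)
  expect_identical(dosages(clean), dosages(out))
  expect_equal(qcReport(clean)$nRemovedMissing + qcReport(clean)$nRemovedMAF, 0)

  expect_error(filterMarkers(out, 0.05, 0.9), "all markers removed")
  empty <- new("MarkerPanel",
               dosages = matrix(numeric(0), 0, 0,
                                dimnames = list(character(0), character(0))),
               ploidyRole = "hybrid", metadata = list())
  expect_error(filterMarkers(empty), "empty")
})

test_that("major-allele imputation fills missing calls deterministically", {
  d <- matrix(c(2, 2, 2, 0, NA,
                0, 0, 2, 2, NA,
                1, 1, 0, 0, 1), nrow = 5,
              dimnames = list(paste0("i", 1:5), c("a", "tie", "clean")))
  panel <- MarkerPanel(d, ploidyRole = "hybrid")
  expect_warning(out <- imputeMajorAllele(panel), "tie")
  expect_equal(dosages(out)[5, "a"], 2)      # major homozygote has dosage 2
  expect_equal(dosages(out)[5, "tie"], 0)    # exact tie resolved to 0
  expect_false(anyNA(dosages(out)))
  # non-missing entries untouched
  expect_identical(dosages(out)[1:4, ], d[1:4, ])
  # no missing entries: identity
  clean <- MarkerPanel(d[, "clean", drop = FALSE], ploidyRole = "hybrid")
  expect_identical(dosages(imputeMajorAllele(clean)), dosages(clean))
  # all-missing marker is an error naming the marker
  d2 <- d; d2[, "a"] <- NA
  expect_error(imputeMajorAllele(MarkerPanel(d2)), "a")
})

test_that("filter + impute leaves no missing entries and no failing marker", {
  set.seed(42)
  d <- matrix(sample(c(0, 1, 2, NA), 60 * 40, TRUE, c(.4, .2, .3, .1)),
              60, 40, dimnames = list(sprintf("h%02d", 1:60),
                                      sprintf("m%02d", 1:40)))
  panel <- filterMarkers(MarkerPanel(d), maxMissingRate = 0.15, minMAF = 0.05)
  # random dosages can tie at exactly 0.5; the tie warning is expected here
  panel <- suppressWarnings(imputeMajorAllele(panel))
  expect_false(anyNA(dosages(panel)))
  expect_true(all(colMeans(is.na(dosages(panel))) < 0.15))
  expect_true(all(.minMAF <- apply(dosages(panel), 2, function(x)
    min(mean(x) / 2, 1 - mean(x) / 2)) >= 0))
})

test_that("half-diallel enumeration gives C(N0,2) ordered pairs", {
  fr <- halfDiallel(paste0("P", 1:5))
  expect_equal(nHybrids(fr), 10)
  pr <- parentPairs(fr)
  expect_true(all(pr[, 1] < pr[, 2]))
  expect_false(any(duplicated(pr)))
  # lexicographic-by-index order
  expect_equal(pr[1:4, 2], 2:5)
  expect_equal(nHybrids(halfDiallel(c("A", "B"))), 1)
  expect_error(halfDiallel(c("A", "A", "B")), "duplicate")
  expect_error(halfDiallel("A"), "at least two")
  # property: N1 = N0 (N0 - 1) / 2 across sizes
  for (n0 in c(3, 7, 24, 60, 142, 200)) {
    expect_equal(nHybrids(halfDiallel(paste0("p", seq_len(n0)))),
                 n0 * (n0 - 1) / 2)
  }
})

test_that("hybrid synthesis averages parental homozygotes and is symmetric", {
  parents <- toyParents()
  fr <- halfDiallel(parents)
  hyb <- synthesizeHybrids(parents, fr)
  d <- dosages(hyb)
  # P1 (0,2,2) x P2 (2,0,2): opposite homozygotes -> het, identical -> same
  expect_equal(unname(d["P1xP2", ]), c(1, 1, 2))
  expect_equal(unname(d["P3xP4", ]), c(1, 1, 1))
  expect_equal(ploidyRole(hyb), "hybrid")
  # symmetry: reversing the parent order leaves genotypes unchanged
  frRev <- halfDiallel(rev(individualIds(parents)))
  hybRev <- synthesizeHybrids(parents, frRev)
  ids <- individualIds(hyb)
  expect_equal(dosages(hybRev)[ids, ], d[ids, ])
  # inbred-with-missing and non-inbred panels are rejected
  dm <- dosages(parents); dm[1, 1] <- NA
  expect_error(synthesizeHybrids(MarkerPanel(dm, "parental_inbred"), fr),
               "impute")
  expect_error(synthesizeHybrids(MarkerPanel(dm, "hybrid"), fr),
               "parental_inbred")
})

test_that("heterozygous parental calls error by default, convert under the permissive flag", {
  d <- matrix(c(0, 2, 1, 2), 2, 2,
              dimnames = list(c("P1", "P2"), c("m1", "m2")))
  expect_error(MarkerPanel(d, "parental_inbred"), "homozygous")
  expect_warning(p <- MarkerPanel(d, "parental_inbred",
                                  onHeterozygote = "missing"),
                 "missing")
  expect_true(is.na(dosages(p)["P1", "m2"]))
})

test_that("additive/dominance coding follows the major/minor orientation", {
  d <- matrix(c(0, 0, 0, 1, 2,    # counted allele rare: f = 0.3 -> minor
                2, 2, 2, 1, 0),   # counted allele common: f = 0.7 -> major
              nrow = 5,
              dimnames = list(paste0("h", 1:5), c("rare", "common")))
  raw <- codeMarkers(MarkerPanel(d))
  # heterozygote: additive 0, dominance 1
  expect_equal(raw$additive[4, ], c(rare = 0, common = 0))
  expect_equal(raw$dominance[4, ], c(rare = 1, common = 1))
  # dosage 2 at a minor-counted marker is the minor homozygote -> -1
  expect_equal(raw$additive[5, "rare"], -1)
  # dosage 0 there is the major homozygote -> +1
  expect_equal(raw$additive[1, "rare"], 1)
  # orientation flips when the counted allele is the major one: dosage 2 is
  # then the major homozygote (+1) and dosage 0 the minor homozygote (-1)
  expect_equal(raw$additive[1, "common"], 1)
  expect_equal(raw$additive[5, "common"], -1)
  # missing entries are rejected with a pointer to imputation
  dm <- d; dm[1, 1] <- NA
  expect_error(codeMarkers(MarkerPanel(dm)), "impute")
})

test_that("hybrid additive score is the midpoint of parental additive scores", {
  parents <- simulateParents(8, 150, seed = 3)
  fr <- halfDiallel(parents)
  hyb <- synthesizeHybrids(parents, fr)
  combined <- MarkerPanel(rbind(dosages(parents), dosages(hyb)),
                          ploidyRole = "hybrid")
  raw <- codeMarkers(combined)
  XA <- raw$additive
  np <- nParents(fr)
  pr <- parentPairs(fr)
  for (k in seq_len(nHybrids(fr))) {
    expect_equal(unname(XA[np + k, ]),
                 unname((XA[pr[k, 1], ] + XA[pr[k, 2], ]) / 2))
  }
})

test_that("zero-dominance columns are removed from both matrices", {
  d <- matrix(c(0, 1, 2,
                0, 2, 2,
                1, 1, 0), nrow = 3,
              dimnames = list(paste0("h", 1:3), c("het", "nohet", "het2")))
  raw <- codeMarkers(MarkerPanel(d))
  out <- dropZeroDominance(raw)
  expect_identical(colnames(out$additive), c("het", "het2"))
  expect_identical(colnames(out$dominance), c("het", "het2"))
  expect_identical(attr(out, "removed"), "nohet")
  # no zero columns -> unchanged
  again <- dropZeroDominance(out)
  expect_identical(again$additive, out$additive)
  # everything removed -> error
  dAll <- matrix(c(0, 2, 2, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(dropZeroDominance(codeMarkers(MarkerPanel(dAll))), "zero dominance")
})

test_that("standardization gives mean 0, sd 1 over reference rows and reuses stats elsewhere", {
  # hand-checked column: {-1, 0, 1} has mean 0, sd 1 with the n-1 divisor
  raw <- list(additive = matrix(c(-1, 0, 1), 3, 1,
                                dimnames = list(c("a", "b", "c"), "m")),
              dominance = matrix(c(0, 1, 0), 3, 1,
                                 dimnames = list(c("a", "b", "c"), "m")))
  cm <- standardizeScores(raw)
  expect_equal(unname(additiveScores(cm)[, 1]), c(-1, 0, 1))
  # dominance column {0,0,1,1}: centred to +-0.5, scaled by its sd
  raw2 <- list(additive = matrix(c(-1, 1, -1, 1), 4, 1,
                                 dimnames = list(letters[1:4], "m")),
               dominance = matrix(c(0, 0, 1, 1), 4, 1,
                                  dimnames = list(letters[1:4], "m")))
  cm2 <- standardizeScores(raw2)
  s <- sd(c(0, 0, 1, 1))
  expect_equal(unname(dominanceScores(cm2)[, 1]), c(-.5, -.5, .5, .5) / s)

  # property: every column has mean 0 and sd 1 over the reference rows
  dat <- makeDiallelData(nParents = 8, nMarkers = 120, seed = 5)
  XA <- additiveScores(dat$coded)
  XD <- dominanceScores(dat$coded)
  expect_lt(max(abs(colMeans(XA))), 1e-10)
  expect_lt(max(abs(colMeans(XD))), 1e-10)
  expect_lt(max(abs(apply(XA, 2, sd) - 1)), 1e-10)
  expect_lt(max(abs(apply(XD, 2, sd) - 1)), 1e-10)

  # non-reference rows are scaled with the reference statistics
  raw3 <- list(additive = matrix(c(-1, 0, 1, 1), 4, 1,
                                 dimnames = list(letters[1:4], "m")),
               dominance = matrix(c(0, 1, 0, 1), 4, 1,
                                  dimnames = list(letters[1:4], "m")))
  cm3 <- standardizeScores(raw3, referenceRows = c("a", "b", "c"))
  st <- columnStats(cm3)$additive
  expect_equal(additiveScores(cm3)["d", 1],
               (1 - st$mean) / st$sd, ignore_attr = TRUE)
  # zero-variance column is an error naming the marker
  rawBad <- list(additive = matrix(1, 3, 1, dimnames = list(letters[1:3], "flat")),
                 dominance = matrix(c(0, 1, 0), 3, 1,
                                    dimnames = list(letters[1:3], "flat")))
  expect_error(standardizeScores(rawBad), "flat")
})
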