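test_that("dataset summaries honor bootstrap multiplicity and nonzero means", {
  p <- makeProfile(matrix(c(2, 0, 4), nrow = 1))
  s <- summarizeDataset(p)
  expect_equal(s@meanAbundance, 3)          # mean of nonzero values
  expect_equal(s@presence, 2 / 3)

  uniform <- summarizeDataset(makeProfile(matrix(c(2, 2, 2), 1)), c(1, 2, 3))
  expect_equal(uniform@meanAbundance, 2)
  expect_equal(uniform@presence, 1)

  allMissing <- summarizeDataset(p, c(2, 2, 2))
  expect_equal(allMissing@meanAbundance, 0)
  expect_equal(allMissing@presence, 0)

  # a repeated replicate counts with its multiplicity
  rep2 <- summarizeDataset(p, c(1, 1, 2))
  expect_equal(rep2@presence, 2 / 3)
  expect_equal(rep2@meanAbundance, 2)

  expect_error(summarizeDataset(p, integer(0)), "empty")
  expect_error(summarizeDataset(p, 9L), "out of range")
})

test_that("original Tanimoto matches closed forms", {
  expect_equal(tanimotoOriginal(makeSummary(c(2, 3), c(1, 1)),
                                makeSummary(c(2, 3), c(1, 1))), 1)
  expect_equal(tanimotoOriginal(makeSummary(c(2, 0), c(1, 0)),
                                makeSummary(c(0, 3), c(0, 1))), 0)
  expect_equal(tanimotoOriginal(makeSummary(2, 1), makeSummary(1, 1)), 2 / 3)
})

test_that("weighted Tanimoto matches hand-computed cases", {
  # one gp, full presence, A=2 B=2: K=2, d=0 -> 1
  expect_equal(tanimotoModified(makeSummary(2, 1), makeSummary(2, 1))@value, 1)

  # one gp, full presence, A=2 B=1: K=2, d=1, num 1, den 4 -> 0.25
  r <- tanimotoModified(makeSummary(2, 1), makeSummary(1, 1))
  expect_equal(r@value, 0.25)
  expect_equal(r@numeratorTerms, 1)

  # two gps: (A=2,P=1 vs B=2,P=0.5) and (A=3,P=1 vs absent) -> 1/6
  a <- makeSummary(c(2, 3), c(1, 1))
  b <- makeSummary(c(2, 0), c(0.5, 0))
  r2 <- tanimotoModified(a, b)
  expect_equal(r2@value, 1 / 6)
  expect_equal(unname(contributionTerms(r2)), c(2, 0))

  # identical full-presence single gp: contribution equals A*B = 4
  expect_equal(unname(contributionTerms(
    tanimotoModified(makeSummary(2, 1), makeSummary(2, 1)))), 4)

  expect_error(tanimotoModified(makeSummary(2, 1),
                                makeSummary(2, 1, ids = "PEPX{9;9;0;0;0}")),
               "not aligned")
  expect_warning(
    empty <- tanimotoModified(makeSummary(0, 0), makeSummary(0, 0)),
    "all-zero")
  expect_equal(empty@value, 1)
  expect_true(empty@bothEmpty)
})

test_that("weighted Tanimoto agrees with an independent transcription", {
  set.seed(101)
  for (i in 1:200) {
    pr <- randomSummaryPair()
    got <- tanimotoModified(pr$a, pr$b)
    expected <- tmodOracle(pr$a@meanAbundance, pr$a@presence,
                           pr$b@meanAbundance, pr$b@presence)
    expect_equal(got@value, expected, tolerance = 1e-12)
    # symmetry and range
    expect_equal(tanimotoModified(pr$b, pr$a)@value, got@value,
                 tolerance = 1e-12)
    expect_gte(got@value, 0)
    expect_lte(got@value, 1)
  }
})

test_that("full presence and equal abundances reduce to the original metric", {
  A <- c(2, 5, 3.5)
  mod <- tanimotoModified(makeSummary(A, rep(1, 3)), makeSummary(A, rep(1, 3)))
  expect_equal(mod@value, 1)
  expect_equal(tanimotoOriginal(makeSummary(A, rep(1, 3)),
                                makeSummary(A, rep(1, 3))), 1)
})

test_that("distance and presence weightings are monotone", {
  # growing |A - B| never increases the similarity
  base <- makeSummary(c(4, 5), c(1, 1))
  vals <- vapply(seq(0, 2, by = 0.25), function(delta)
    tanimotoModified(base, makeSummary(c(4 + delta, 5), c(1, 1)))@value, 0)
  expect_true(all(diff(vals) <= 1e-12))

  # lowering either presence never increases that gp's numerator term
  terms <- vapply(c(1, 0.75, 0.5, 0.25), function(p)
    tanimotoModified(makeSummary(4, 1, n = 4L),
                     makeSummary(4, p, n = 4L))@numeratorTerms, 0)
  expect_true(all(diff(terms) <= 1e-12))
})

test_that("global-K mode uses one shared distance base", {
  a <- makeSummary(c(6, 2), c(1, 1), n = 4L)
  b <- makeSummary(c(5, 2), c(0.25, 1), n = 4L)
  perGp <- tanimotoModified(a, b)
  glob <- tanimotoModified(a, b, kMode = "global")
  Kg <- 1 + mean(c(a@presence, b@presence))
  numOracle <- sum(a@meanAbundance * a@presence * b@meanAbundance *
                     b@presence * Kg^(-abs(a@meanAbundance - b@meanAbundance)))
  denOracle <- sum((a@meanAbundance * a@presence)^2) +
    sum((b@meanAbundance * b@presence)^2) - numOracle
  expect_equal(glob@value, numOracle / denOracle, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(glob@value, perGp@value)))
})
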