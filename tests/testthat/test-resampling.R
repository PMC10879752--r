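test_that("test collections draw, canonicalize and deduplicate samplings", {
  p <- makeProfile(matrix(stats::runif(15, 2, 8), 5), group = "A")
  coll <- buildTestCollection(p, nSamplings = 500L, seed = 3L)
  expect_true(all(lengths(coll@samplings) == 3L))
  # at most choose(3+3-1, 3) = 10 distinct multisets from 3 replicates
  expect_lte(length(coll@samplings), length(enumerateMultisets(3L, 3L)))
  expect_equal(length(enumerateMultisets(3L, 3L)), 10L)
  keys <- vapply(coll@samplings, paste, "", collapse = ",")
  expect_false(anyDuplicated(keys) > 0)

  # determinism under a fixed seed
  coll2 <- buildTestCollection(p, nSamplings = 500L, seed = 3L)
  expect_identical(coll@samplings, coll2@samplings)
  expect_identical(coll@means, coll2@means)

  one <- makeProfile(matrix(c(2, 3), 2), group = "A")
  expect_error(buildTestCollection(one), "at least 2 replicates")
})

test_that("null samplings balance group draw counts to within one", {
  a <- makeProfile(matrix(stats::runif(32, 2, 8), 8), group = "A")  # 4 reps
  b <- makeProfile(matrix(stats::runif(32, 2, 8), 8), group = "B")
  nulls <- buildNullCollections(a, b, nSamplings = 100L, seed = 9L)
  for (s in c(nulls$a@samplings, nulls$b@samplings)) {
    expect_length(s, 4L)
    fromA <- sum(s <= 4L)
    expect_equal(fromA, 2L)   # even size: exactly half from each group
  }

  # odd group size: (2,1) or (1,2)
  a3 <- makeProfile(matrix(stats::runif(24, 2, 8), 8), group = "A")
  nulls3 <- buildNullCollections(a3, b, nSamplings = 100L, seed = 9L)
  for (s in nulls3$a@samplings) {
    expect_length(s, 3L)
    expect_lte(abs(sum(s <= 3L) - sum(s > 3L)), 1L)
  }

  nulls2 <- buildNullCollections(a, b, nSamplings = 100L, seed = 9L)
  expect_identical(nulls$a@samplings, nulls2$a@samplings)
  expect_identical(nulls$b@samplings, nulls2$b@samplings)
})

test_that("comparison counts follow the pairing identities", {
  p <- makeProfile(matrix(stats::runif(40, 2, 8), 5, 8), group = "A")
  # explicit collections of known sizes via enumerated distinct multisets
  ms <- enumerateMultisets(8L, 2L)   # samplings of size 2 for compact counts
  mkColl <- function(m) {
    sel <- lapply(ms[seq_len(m)], function(s) s)
    cl <- samplingCollection(makeProfile(abundanceMatrix(p)[, 1:8],
                                         group = "A"), sel)
    cl
  }
  expect_length(internalDistribution(mkColl(2L)), 1L)
  expect_length(internalDistribution(mkColl(10L)), choose(10L, 2L))
  expect_length(testDistribution(mkColl(10L), mkColl(7L)), 70L)
  expect_length(nullDistribution(mkColl(2L), mkColl(3L)), 6L)
  expect_error(internalDistribution(mkColl(1L)), "at least 2")

  # property: counts hold across random collection sizes
  set.seed(11)
  for (i in 1:5) {
    ka <- sample(2:20, 1L); kb <- sample(2:20, 1L)
    expect_length(internalDistribution(mkColl(ka)), choose(ka, 2L))
    expect_length(testDistribution(mkColl(ka), mkColl(kb)), ka * kb)
  }
})

test_that("distributions are invariant to replicate column order", {
  set.seed(21)
  m <- matrix(stats::runif(18, 2, 8), 6)
  m[sample(length(m), 5L)] <- 0
  p1 <- makeProfile(m, group = "A")
  p2 <- makeProfile(m[, c(3, 1, 2)], group = "A")
  # saturate all 10 distinct multisets so the collections coincide as sets
  d1 <- internalDistribution(buildTestCollection(p1, 2000L, seed = 1L))
  d2 <- internalDistribution(buildTestCollection(p2, 2000L, seed = 2L))
  expect_length(d1, choose(10L, 2L))
  expect_equal(sort(d1), sort(d2), tolerance = 1e-12)
})

test_that("null distribution of identical groups concentrates near internal", {
  sc <- simulateScenario(presetScenario("iid", seed = 31L))
  dist <- contextualSimilarity(sc$a, sc$b, nTest = 50L, nNull = 100L,
                               seed = 31L)
  internal <- c(dist@internalA, dist@internalB)
  expect_lt(abs(mean(dist@null) - mean(internal)), 2 * stats::sd(internal))
})

test_that("observed similarity matches the summary-level metric", {
  p <- makeProfile(matrix(c(2, 4, 3, 5), 2), group = "A")
  expect_equal(observedSimilarity(p, p), 1)

  a <- makeProfile(rbind(c(5, 5), c(0, 0)), group = "A")
  b <- makeProfile(rbind(c(0, 0), c(4, 4)), group = "B")
  expect_equal(observedSimilarity(a, b), 0)

  # the two-gp worked example: 1/6
  a2 <- makeProfile(rbind(c(2, 2), c(3, 3)), group = "A")
  b2 <- makeProfile(rbind(c(2, 0), c(0, 0)), group = "B")
  expect_equal(observedSimilarity(a2, b2), 1 / 6)
})

test_that("the full resampling stage is deterministic under a seed", {
  sc <- simulateScenario(presetScenario("none", seed = 17L))
  d1 <- contextualSimilarity(sc$a, sc$b, nTest = 30L, nNull = 40L, seed = 5L)
  d2 <- contextualSimilarity(sc$a, sc$b, nTest = 30L, nNull = 40L, seed = 5L)
  expect_identical(d1@test, d2@test)
  expect_identical(d1@null, d2@null)
  expect_identical(d1@internalA, d2@internalA)
  expect_identical(d1@contribNull, d2@contribNull)

  f <- withr::local_tempfile(fileext = ".tsv")
  writeDistributions(d1, f)
  lines <- readLines(f)
  expect_match(lines[1L], "seed: 5")
  expect_equal(length(lines) - 3L,
               length(d1@internalA) + length(d1@internalB) +
                 length(d1@test) + length(d1@null))
})
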