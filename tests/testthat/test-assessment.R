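test_that("density estimates integrate to one and flag degeneracy", {
  set.seed(41)
  d <- estimateDensity(stats::runif(500))
  expect_equal(glycontext:::.trapz(d@grid, d@density), 1, tolerance = 1e-9)
  expect_false(d@degenerate)

  spike <- estimateDensity(rep(0.5, 10))
  expect_true(spike@degenerate)
  expect_equal(glycontext:::.trapz(spike@grid, spike@density), 1,
               tolerance = 1e-9)

  # two separated clusters give a bimodal estimate (sign-change oracle)
  vals <- c(stats::rnorm(400, 0.25, 0.03), stats::rnorm(400, 0.75, 0.03))
  db <- estimateDensity(vals)
  slope <- sign(diff(db@density))
  nMaxima <- sum(diff(slope) < 0)
  expect_gte(nMaxima, 2L)

  expect_error(estimateDensity(0.4), "at least 2")
})

test_that("alpha/beta overlap behaves at the analytic extremes", {
  set.seed(43)
  # disjoint supports: both rates exactly zero
  lo <- estimateDensity(stats::rnorm(2000, 0.15, 0.02))
  hi <- estimateDensity(stats::rnorm(2000, 0.85, 0.02))
  ov <- alphaBetaOverlap(lo, hi)
  expect_equal(ov@alpha, 0, tolerance = 1e-6)
  expect_equal(ov@beta, 0, tolerance = 1e-6)

  # identical distributions: crossing at the common mean, alpha = beta ~ 0.5
  x <- stats::rnorm(3000, 0.5, 0.05)
  dx <- estimateDensity(x)
  ovSame <- alphaBetaOverlap(dx, dx)
  expect_equal(ovSame@alpha, ovSame@beta, tolerance = 0.05)
  expect_equal(ovSame@alpha, 0.5, tolerance = 0.05)

  # samples six sigma apart: both rates < 1%
  a6 <- estimateDensity(stats::rnorm(5000, 0.3, 0.05))
  b6 <- estimateDensity(stats::rnorm(5000, 0.6, 0.05))
  ov6 <- alphaBetaOverlap(a6, b6)
  expect_lt(ov6@alpha, 0.01)
  expect_lt(ov6@beta, 0.01)

  # orientation swap is flagged when the reference sits below the test
  ovSwap <- alphaBetaOverlap(hi, lo)
  expect_true(ovSwap@swapped)
  expect_equal(ovSwap@alpha, ov@alpha, tolerance = 1e-12)

  # degenerate spikes: distinct -> 0/0, identical -> 0.5/0.5
  s1 <- estimateDensity(rep(0.2, 5)); s2 <- estimateDensity(rep(0.8, 5))
  expect_equal(alphaBetaOverlap(s1, s2)@alpha, 0)
  expect_equal(alphaBetaOverlap(s1, s1)@alpha, 0.5)
})

test_that("internal confidence matches its closed form", {
  internal <- c(0.9 - 0.06 / sqrt(2), 0.9 + 0.06 / sqrt(2))  # mean .9, sd .06
  test <- c(0.55, 0.6, 0.65)                                  # mean 0.6
  noOverlap <- methods::new("OverlapResult", alpha = 0, beta = 0,
                            crossing = 0.75, swapped = FALSE)
  expect_equal(as.numeric(internalConfidence(internal, test,
                                             overlap = noOverlap)),
               5, tolerance = 1e-9)

  fullOverlap <- methods::new("OverlapResult", alpha = 0.5, beta = 0.5,
                              crossing = 0.75, swapped = FALSE)
  expect_equal(as.numeric(internalConfidence(internal, test,
                                             overlap = fullOverlap)),
               0.5, tolerance = 1e-9)

  # equal means give IC = 0 regardless of overlap
  expect_equal(as.numeric(internalConfidence(c(0.5, 0.7), c(0.55, 0.65),
                                             overlap = noOverlap)),
               0, tolerance = 1e-9)

  # IC decreases strictly as alpha + beta grows, means and sd fixed
  ics <- vapply(seq(0, 1, by = 0.25), function(s)
    as.numeric(internalConfidence(internal, test,
      overlap = methods::new("OverlapResult", alpha = s / 2, beta = s / 2,
                             crossing = 0.7, swapped = FALSE))), 0)
  expect_true(all(diff(ics) < 0))

  expect_error(internalConfidence(rep(0.5, 5), test), "degenerate internal")
})

test_that("observed validity applies the 3-SD and central-quartile gates", {
  set.seed(47)
  test <- stats::rnorm(2000, 0.7, 0.05)
  atMean <- observedValidity(mean(test), test)
  expect_equal(atMean$z, 0, tolerance = 1e-9)
  expect_true(atMean$valid)

  far <- observedValidity(mean(test) + 4 * stats::sd(test), test)
  expect_false(far$valid)
  expect_equal(far$z, 4, tolerance = 1e-9)

  p60 <- stats::quantile(test, 0.60, names = FALSE)
  expect_true(observedValidity(p60, test, mode = "central_quartile")$valid)
  p90 <- stats::quantile(test, 0.90, names = FALSE)
  expect_false(observedValidity(p90, test, mode = "central_quartile")$valid)
})

test_that("general comparison decides differentiability by overlap", {
  set.seed(53)
  same <- stats::rnorm(1000, 0.6, 0.04)
  gSame <- generalComparison(same, same)
  expect_false(gSame$differentiable)

  test <- stats::rnorm(1000, 0.2, 0.02)
  null <- stats::rnorm(1000, 0.8, 0.02)
  gDisj <- generalComparison(test, null)
  expect_true(gDisj$differentiable)
  expect_equal(gDisj$alpha, 0, tolerance = 1e-6)
  expect_equal(gDisj$beta, 0, tolerance = 1e-6)
  expect_false(gDisj$nullBelowTest)
  expect_true(generalComparison(null, test)$nullBelowTest)
})

test_that("outlier detection flags a replicate that splits the comparisons", {
  # 4 replicates, all 35 distinct bootstrap multisets, all pairs; comparisons
  # touching replicate 1 are systematically less similar
  set.seed(59)
  samplings <- enumerateMultisets(4L, 4L)
  k <- length(samplings)
  pairs <- utils::combn(k, 2L)
  touches1 <- vapply(samplings, function(s) 1L %in% s, TRUE)
  low <- touches1[pairs[1L, ]] | touches1[pairs[2L, ]]
  values <- ifelse(low, stats::rnorm(ncol(pairs), 0.5, 0.02),
                   stats::rnorm(ncol(pairs), 0.9, 0.01))
  det <- detectOutlierReplicates(values, pairs, samplings, 4L)
  expect_false(det$unimodal)
  v <- det$verdicts
  expect_true(any(v$replicate == 1L & v$removal_recommended))
  # replicate 1 is under-represented in the primary (high-similarity) peak
  prim <- det$peaks$peak[det$peaks$primary]
  expect_true(any(v$replicate == 1L & v$peak == prim & v$direction == "under"))
  expect_false(any(v$removal_recommended & v$replicate != 1L))
})

test_that("outlier detection stays quiet on unimodal and gated structures", {
  set.seed(61)
  samplings <- enumerateMultisets(4L, 4L)
  pairs <- utils::combn(length(samplings), 2L)
  flat <- stats::rnorm(ncol(pairs), 0.8, 0.01)
  detFlat <- detectOutlierReplicates(flat, pairs, samplings, 4L)
  expect_true(detFlat$unimodal)
  expect_equal(nrow(detFlat$verdicts), 0L)

  # a secondary peak holding ~8% of comparisons is ignored by the mass gate,
  # even though its members all touch replicate 1
  touches1 <- vapply(samplings, function(s) 1L %in% s, TRUE)
  eligibleLow <- which(touches1[pairs[1L, ]] | touches1[pairs[2L, ]])
  lowIdx <- sample(eligibleLow, round(0.08 * ncol(pairs)))
  gated <- stats::rnorm(ncol(pairs), 0.85, 0.01)
  gated[lowIdx] <- stats::rnorm(length(lowIdx), 0.3, 0.01)
  detGate <- detectOutlierReplicates(gated, pairs, samplings, 4L)
  expect_false(any(detGate$verdicts$peak != detGate$peaks$peak[detGate$peaks$primary]))
})

test_that("interchangeable replicates are essentially never flagged", {
  flagged <- 0L
  for (s in 1:10) {
    sc <- simulateScenario(presetScenario("iid", seed = s))
    coll <- buildTestCollection(sc$a, 100L, seed = s + 500L)
    rec <- glycontext:::.internalRecords(coll)
    det <- detectOutlierReplicates(rec$values, rec$pairs, coll@samplings, 4L)
    if (any(det$verdicts$removal_recommended)) flagged <- flagged + 1L
  }
  expect_lte(flagged, 1L)
})

test_that("assessQuality assembles a coherent report on a clear separation", {
  sc <- simulateScenario(presetScenario("exclusive", seed = 7L))
  dist <- contextualSimilarity(sc$a, sc$b, nTest = 50L, nNull = 100L, seed = 7L)
  rep <- assessQuality(dist)
  expect_s4_class(rep, "QualityReport")
  expect_true(rep@differentiable)
  expect_identical(rep@status, "differentiable")
  expect_gte(rep@icA, 2)
  expect_gte(rep@icB, 2)
  # the report invariant: differentiable implies sub-threshold overlap
  expect_lt(rep@general@alpha, rep@thresholds$alpha)
  expect_lt(rep@general@beta, rep@thresholds$beta)
})

test_that("labels A and B are exchangeable for identically generated groups", {
  sc <- simulateScenario(presetScenario("none", seed = 13L))
  d1 <- contextualSimilarity(sc$a, sc$b, nTest = 40L, nNull = 60L, seed = 2L)
  d2 <- contextualSimilarity(sc$b, sc$a, nTest = 40L, nNull = 60L, seed = 2L)
  g1 <- generalComparison(d1@test, d1@null)
  g2 <- generalComparison(d2@test, d2@null)
  expect_equal(g1$alpha, g2$alpha, tolerance = 0.1)
  expect_equal(g1$beta, g2$beta, tolerance = 0.1)
  expect_identical(g1$differentiable, g2$differentiable)
})
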