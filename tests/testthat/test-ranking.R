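# A compact comparison where glycopeptide 6 is stable within both groups but
# shifted between them; the rest are identical across groups.
shiftFixture <- function(seedA = 10L, seedB = 20L, seed = 3L) {
  ids <- sprintf("PEP{%d;2;0;0;0}", 3:8)
  shared <- matrix(rep(c(5, 6, 7, 5.5, 6.5), 4L), 5L)
  mk <- function(seed, shiftTo) {
    set.seed(seed)
    m <- rbind(shared + stats::rnorm(20L, 0, 0.05),
               shiftTo + stats::rnorm(4L, 0, 0.05))
    dimnames(m) <- list(ids, paste0("r", 1:4, "_", seed))
    m
  }
  a <- glycoProfile(mk(seedA, 6), "A", standardized = TRUE)
  b <- glycoProfile(mk(seedB, 4), "B", standardized = TRUE)
  contextualSimilarity(a, b, nTest = 40L, nNull = 80L, seed = seed)
}

test_that("a stable between-group shift is top-ranked and passes quality", {
  d <- shiftFixture()
  r <- rankGlycopeptides(d)
  shifted <- "PEP{8;2;0;0;0}"
  expect_identical(r$glycopeptide[1L], shifted)
  expect_lt(r$z_score[1L], -2)
  expect_true(r$quality_pass[r$glycopeptide == shifted])
  expect_identical(r$likely_failure_cause[r$glycopeptide == shifted], "Passed")
  # glycopeptides identical across groups cannot separate their internal and
  # test contributions and fail the combined overlap gate
  expect_true(all(grepl("LowQuality", r$likely_failure_cause[
    r$glycopeptide != shifted])))
  # near-zero contributors rank last
  expect_gt(r$z_score[nrow(r)], -1)
})

test_that("group-exclusive glycopeptides get negative z and UnseenIn_File2", {
  sc <- simulateScenario(presetScenario("exclusive", seed = 7L))
  d <- contextualSimilarity(sc$a, sc$b, nTest = 50L, nNull = 100L, seed = 7L)
  r <- rankGlycopeptides(d)
  excl <- r[r$glycopeptide %in% sc$exclusive, ]
  expect_equal(nrow(excl), length(sc$exclusive))
  expect_true(all(excl$likely_failure_cause == "UnseenIn_File2"))
  expect_true(all(excl$z_score < 0))
  expect_true(all(excl$presence_b == 0))
  # all exclusive gps outrank all shared ones
  shared <- r$z_score[!r$glycopeptide %in% sc$exclusive]
  expect_lt(max(excl$z_score), min(shared))
})

test_that("a glycopeptide absent from both groups is never ranked", {
  ids <- sprintf("PEP{%d;2;0;0;0}", 3:6)
  m <- matrix(stats::runif(12, 5, 7), 3L)
  mk <- function(g) {
    mm <- rbind(m, 0)
    dimnames(mm) <- list(ids, paste0(g, 1:4))
    glycoProfile(mm, g, standardized = TRUE)
  }
  d <- contextualSimilarity(mk("A"), mk("B"), nTest = 30L, nNull = 40L,
                            seed = 2L)
  r <- rankGlycopeptides(d)
  expect_false("PEP{6;2;0;0;0}" %in% r$glycopeptide)
  expect_equal(nrow(r), 3L)
  expect_true(all(is.finite(r$z_score)))
})

test_that("ranking is stable under duplication of a non-informative gp", {
  d <- shiftFixture()
  base <- rankGlycopeptides(d)$glycopeptide
  ids2 <- c(sprintf("PEP{%d;2;0;0;0}", 3:8), "PEP{9;9;9;9;9}")
  mk <- function(seed, shiftTo) {
    set.seed(seed)
    shared <- matrix(rep(c(5, 6, 7, 5.5, 6.5), 4L), 5L)
    m <- rbind(shared + stats::rnorm(20L, 0, 0.05),
               shiftTo + stats::rnorm(4L, 0, 0.05),
               6)  # constant everywhere in both groups
    dimnames(m) <- list(ids2, paste0("r", 1:4, "_", seed))
    m
  }
  a <- glycoProfile(mk(10L, 6), "A", standardized = TRUE)
  b <- glycoProfile(mk(20L, 4), "B", standardized = TRUE)
  d2 <- contextualSimilarity(a, b, nTest = 40L, nNull = 80L, seed = 3L)
  r2 <- rankGlycopeptides(d2)
  kept <- r2$glycopeptide[r2$glycopeptide %in% base]
  expect_identical(kept, base)
})

test_that("a zero-spread null contribution is flagged DegenerateNull", {
  ids <- sprintf("PEP{%d;2;0;0;0}", 3:5)
  mk <- function(g) {
    m <- matrix(c(5, 6, 7), 3L, 4L)   # no noise at all
    dimnames(m) <- list(ids, paste0(g, 1:4))
    glycoProfile(m, g, standardized = TRUE)
  }
  d <- contextualSimilarity(mk("A"), mk("B"), nTest = 20L, nNull = 30L,
                            seed = 4L)
  r <- rankGlycopeptides(d)
  expect_true(all(r$likely_failure_cause == "DegenerateNull"))
  expect_true(all(is.finite(r$z_score)))
  expect_true(all(abs(r$z_score) < 1e-6))

  f <- withr::local_tempfile(fileext = ".tsv")
  writeRankingTable(r, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), 3L)
  expect_identical(colnames(back)[1:2], c("glycopeptide", "z_score"))
})
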