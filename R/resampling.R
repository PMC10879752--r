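# Bootstrap collections and the four contextual similarity distributions.

# Build the per-sampling summary matrices for a list of samplings over a
# value matrix (glycopeptide x replicates).
.collectionFromSamplings <- function(values, samplings, label) {
  k <- length(samplings)
  means <- matrix(0, nrow = nrow(values), ncol = k,
                  dimnames = list(rownames(values), NULL))
  pres <- means
  for (j in seq_len(k)) {
    v <- values[, samplings[[j]], drop = FALSE]
    cnt <- rowSums(v > 0)
    means[, j] <- ifelse(cnt > 0, rowSums(v) / pmax(cnt, 1L), 0)
    pres[, j] <- cnt / length(samplings[[j]])
  }
  methods::new("SamplingCollection", sourceLabel = label, samplings = samplings,
               means = means, presence = pres, ids = rownames(values),
               nReplicates = if (k) length(samplings[[1L]]) else 0L)
}

#' Construct a sampling collection from explicit samplings
#'
#' Lower-level constructor used when the samplings are supplied directly
#' (e.g. an exhaustive enumeration of distinct multisets) rather than drawn.
#' Samplings are canonicalized (sorted) and deduplicated, preserving first
#' occurrence order.
#'
#' @param x a standardized [GlycoProfile-class] providing the value matrix.
#' @param samplings list of integer vectors of replicate indices, all of the
#'   same length.
#' @param label source label.
#' @return A [SamplingCollection-class].
#' @export
samplingCollection <- function(x, samplings, label = groupLabel(x)) {
  samplings <- lapply(samplings, function(s) sort(as.integer(s)))
  keys <- vapply(samplings, .samplingKey, "")
  samplings <- samplings[!duplicated(keys)]
  .collectionFromSamplings(abundanceMatrix(x), samplings, label)
}

#' Build a test collection by bootstrap resampling one group
#'
#' Draws `nSamplings` multisets of replicate indices with replacement, each
#' of the group's replicate count, canonicalizes them as sorted tuples and
#' removes duplicates. Deterministic under `seed`. With few replicates the
#' number of distinct multisets is combinatorially capped (e.g. 10 for three
#' replicates), so the collection may be much smaller than `nSamplings`.
#'
#' @param x standardized [GlycoProfile-class] with at least 2 replicates.
#' @param nSamplings draws before duplicate reduction (default 100).
#' @param seed integer RNG seed.
#' @return A [SamplingCollection-class].
#' @export
buildTestCollection <- function(x, nSamplings = 100L, seed = 1L) {
  n <- ncol(x)
  if (n < 2L)
    stop("at least 2 replicates are needed to measure internal variability",
         call. = FALSE)
  samplings <- .withSeed(seed, replicate(nSamplings,
                                         sort(sample.int(n, n, replace = TRUE)),
                                         simplify = FALSE))
  samplingCollection(x, samplings, label = groupLabel(x))
}

#' Build the two null collections from the pooled groups
#'
#' Null samplings draw from the pooled replicates of both groups with
#' replacement, with sizes matching group A's and group B's replicate counts
#' respectively. Draw counts are balanced between the groups to within one
#' (alternating halves; for odd sizes the extra draw goes to a uniformly
#' random group) so that neither group's outliers dominate a null dataset.
#' Duplicate multisets are removed. Replicate indices in the returned
#' collections refer to the pooled column order `A then B`.
#'
#' @param a,b standardized, aligned [GlycoProfile-class] objects, each with
#'   at least 2 replicates.
#' @param nSamplings draws per collection before duplicate reduction
#'   (default 200).
#' @param seed integer RNG seed.
#' @return list with [SamplingCollection-class] elements `a` and `b` (sized
#'   like groups A and B) and the pooled value matrix as attribute access is
#'   not needed downstream.
#' @export
buildNullCollections <- function(a, b, nSamplings = 200L, seed = 1L) {
  ma <- abundanceMatrix(a); mb <- abundanceMatrix(b)
  .assertAligned(rownames(ma), rownames(mb), "profiles")
  nA <- ncol(ma); nB <- ncol(mb)
  if (nA < 2L || nB < 2L)
    stop("at least 2 replicates per group are needed", call. = FALSE)
  pooled <- cbind(ma, mb)
  colnames(pooled) <- make.unique(colnames(pooled))
  drawBalanced <- function(size) {
    cA <- size %/% 2L
    if (size %% 2L == 1L && sample.int(2L, 1L) == 1L) cA <- cA + 1L
    cB <- size - cA
    sort(c(sample.int(nA, cA, replace = TRUE),
           nA + sample.int(nB, cB, replace = TRUE)))
  }
  pooledProfile <- glycoProfile(pooled, group = "pooled", standardized = TRUE)
  .withSeed(seed, {
    sA <- replicate(nSamplings, drawBalanced(nA), simplify = FALSE)
    sB <- replicate(nSamplings, drawBalanced(nB), simplify = FALSE)
    list(a = samplingCollection(pooledProfile, sA, label = "null_A"),
         b = samplingCollection(pooledProfile, sB, label = "null_B"))
  })
}

# Compare selected sampling pairs between (possibly identical) collections.
.comparePairs <- function(ca, cb, ia, ib) {
  res <- .pairSimilarity(ca@means[, ia, drop = FALSE],
                         ca@presence[, ia, drop = FALSE],
                         cb@means[, ib, drop = FALSE],
                         cb@presence[, ib, drop = FALSE])
  list(values = res$value, pairs = rbind(ia, ib), contrib = res$num)
}

.internalRecords <- function(collection) {
  k <- length(collection@samplings)
  if (k < 2L)
    stop("at least 2 distinct samplings are needed for an internal ",
         "distribution", call. = FALSE)
  pairs <- utils::combn(k, 2L)
  .comparePairs(collection, collection, pairs[1L, ], pairs[2L, ])
}

.crossRecords <- function(ca, cb) {
  ka <- length(ca@samplings); kb <- length(cb@samplings)
  if (ka < 1L || kb < 1L) stop("empty sampling collection", call. = FALSE)
  ia <- rep(seq_len(ka), each = kb)
  ib <- rep(seq_len(kb), times = ka)
  .comparePairs(ca, cb, ia, ib)
}

#' Internal similarity distribution of one collection
#'
#' Weighted Tanimoto over all unordered distinct pairs of samplings within
#' one collection: `choose(k, 2)` comparisons for `k` distinct samplings
#' (4950 at the default cap of 100).
#'
#' @param collection a [SamplingCollection-class] with at least 2 samplings.
#' @return numeric vector of similarity values.
#' @export
internalDistribution <- function(collection) .internalRecords(collection)$values

#' Test similarity distribution between two test collections
#'
#' All cross pairs: `k_a * k_b` comparisons (10 000 at the default caps).
#'
#' @param ca,cb [SamplingCollection-class] objects built from the two groups.
#' @return numeric vector of similarity values.
#' @export
testDistribution <- function(ca, cb) .crossRecords(ca, cb)$values

#' Null similarity distribution between the two null collections
#'
#' All cross pairs of the two pooled-resampling collections: up to 40 000
#' comparisons at the default caps of 200 samplings per side.
#'
#' @param na,nb null [SamplingCollection-class] objects from
#'   [buildNullCollections()].
#' @return numeric vector of similarity values.
#' @export
nullDistribution <- function(na, nb) .crossRecords(na, nb)$values

#' Observed (unsampled) similarity between the two groups
#'
#' The single weighted Tanimoto comparison of the full, unresampled
#' summaries; used downstream to validate that the bootstrap simulated the
#' original comparison faithfully.
#'
#' @param a,b standardized, aligned [GlycoProfile-class] objects.
#' @return numeric scalar in \[0,1\].
#' @export
observedSimilarity <- function(a, b) {
  tanimotoModified(summarizeDataset(a), summarizeDataset(b))@value
}

#' Compute the full set of contextual similarity distributions
#'
#' Orchestrates the resampling stage: builds the two test collections and
#' the two null collections, evaluates the Internal-A, Internal-B, Test and
#' Null similarity distributions with their per-comparison contribution
#' records, and the Observed similarity. A single seeded RNG stream drives
#' all sampling (test A, test B, then the nulls), so the result is fully
#' deterministic under `seed`.
#'
#' @param a,b standardized, aligned [GlycoProfile-class] objects.
#' @param nTest test-collection draws per group before deduplication
#'   (default 100).
#' @param nNull null-collection draws per side before deduplication
#'   (default 200).
#' @param seed integer seed.
#' @return A [SimilarityDistributions-class].
#' @export
contextualSimilarity <- function(a, b, nTest = 100L, nNull = 200L, seed = 1L) {
  .assertAligned(rownames(a), rownames(b), "profiles")
  seed <- as.integer(seed)
  ca <- buildTestCollection(a, nTest, seed = seed)
  cb <- buildTestCollection(b, nTest, seed = seed + 1L)
  nulls <- buildNullCollections(a, b, nNull, seed = seed + 2L)
  intA <- .internalRecords(ca)
  intB <- .internalRecords(cb)
  tst <- .crossRecords(ca, cb)
  nul <- .crossRecords(nulls$a, nulls$b)
  obs <- tanimotoModified(summarizeDataset(a), summarizeDataset(b))
  methods::new("SimilarityDistributions",
               internalA = intA$values, internalB = intB$values,
               test = tst$values, null = nul$values,
               pairsInternalA = intA$pairs, pairsInternalB = intB$pairs,
               pairsTest = tst$pairs, pairsNull = nul$pairs,
               contribInternalA = intA$contrib, contribInternalB = intB$contrib,
               contribTest = tst$contrib, contribNull = nul$contrib,
               observed = obs,
               summaryA = summarizeDataset(a), summaryB = summarizeDataset(b),
               collections = list(testA = ca, testB = cb,
                                  nullA = nulls$a, nullB = nulls$b),
               ids = rownames(a), seed = seed)
}

setMethod("show", "SimilarityDistributions", function(object) {
  cat("SimilarityDistributions (seed ", object@seed, ")\n", sep = "")
  cat(sprintf("  Internal A: %5d comparisons, mean %.3f\n",
              length(object@internalA), mean(object@internalA)))
  cat(sprintf("  Internal B: %5d comparisons, mean %.3f\n",
              length(object@internalB), mean(object@internalB)))
  cat(sprintf("  Test:       %5d comparisons, mean %.3f\n",
              length(object@test), mean(object@test)))
  cat(sprintf("  Null:       %5d comparisons, mean %.3f\n",
              length(object@null), mean(object@null)))
  cat(sprintf("  Observed similarity: %.4f\n", object@observed@value))
  invisible(NULL)
})

#' Serialize similarity distributions for audit
#'
#' Writes one row per comparison (`comparison_kind`, `sampling_a`,
#' `sampling_b`, `similarity`) to a TSV whose header comment records the
#' seed.
#'
#' @param dist a [SimilarityDistributions-class].
#' @param file output path.
#' @export
writeDistributions <- function(dist, file) {
  rows <- function(kind, values, pairs)
    data.frame(comparison_kind = kind,
               sampling_a = pairs[1L, ], sampling_b = pairs[2L, ],
               similarity = values, stringsAsFactors = FALSE)
  df <- rbind(rows("internal_a", dist@internalA, dist@pairsInternalA),
              rows("internal_b", dist@internalB, dist@pairsInternalB),
              rows("test", dist@test, dist@pairsTest),
              rows("null", dist@null, dist@pairsNull))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", dist@seed), con)
  writeLines(sprintf("# observed_similarity: %.12g", dist@observed@value), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
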