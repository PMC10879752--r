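# End-to-end orchestration of the six-step comparison workflow.

.reportToList <- function(report, dist, ranking) {
  ov <- function(o) list(alpha = o@alpha, beta = o@beta,
                         fpr_percent = 100 * o@alpha,
                         fnr_percent = 100 * o@beta,
                         crossing = o@crossing, swapped = o@swapped)
  list(
    schema_version = "1.0",
    seed = dist@seed,
    status = report@status,
    differentiable = report@differentiable,
    thresholds = report@thresholds,
    internal_confidence = list(group_a = report@icA, group_b = report@icB),
    quality_pass = list(group_a = report@qualityPassA,
                        group_b = report@qualityPassB),
    overlap_internal_vs_test = list(group_a = ov(report@overlapA),
                                    group_b = ov(report@overlapB)),
    general_comparison = ov(report@general),
    observed = list(similarity = dist@observed@value, z = report@observedZ,
                    valid = report@observedValid),
    null_below_test = report@nullBelowTest,
    comparison_counts = list(internal_a = length(dist@internalA),
                             internal_b = length(dist@internalB),
                             test = length(dist@test),
                             null = length(dist@null)),
    outliers = list(group_a = report@outliersA, group_b = report@outliersB),
    narrative = report@narrative,
    ranking = ranking)
}

.removeReplicates <- function(x, drop) {
  m <- abundanceMatrix(x)
  keep <- setdiff(seq_len(ncol(m)), drop)
  if (length(keep) < 2L)
    stop("outlier removal would leave fewer than 2 replicates", call. = FALSE)
  tic <- ticValues(x)
  glycoProfile(m[, keep, drop = FALSE], group = groupLabel(x),
               tic = if (is.null(tic)) NULL else tic[keep],
               standardized = isStandardized(x))
}

.runOnce <- function(a, b, nTest, nNull, seed, icGate, alphaThreshold,
                     betaThreshold, perGpThreshold, observedMode) {
  dist <- contextualSimilarity(a, b, nTest = nTest, nNull = nNull, seed = seed)
  report <- assessQuality(dist, icGate = icGate,
                          alphaThreshold = alphaThreshold,
                          betaThreshold = betaThreshold,
                          observedMode = observedMode)
  ranking <- rankGlycopeptides(dist, combinedThreshold = perGpThreshold)
  list(dist = dist, report = report, ranking = ranking)
}

#' Run the full comparison workflow
#'
#' Executes the six-step pipeline on two sample groups: (1) alignment and
#' minimum-observation filtering (with optional between-group rescaling),
#' (2) bootstrap collection building, (3) the four similarity distributions
#' plus the Observed similarity, (4) quality assessment (ICs, overlap rates,
#' replicate outliers, Observed validity, Null sanity), (5) the general
#' Test-vs-Null differentiability decision, and (6) contribution ranking
#' with failure causes. If the first pass recommends replicate removal, the
#' pipeline reruns once without those replicates (a single, non-iterative
#' removal to avoid data dredging) and reports both passes.
#'
#' @param a,b standardized [GlycoProfile-class] objects (not yet aligned).
#' @param seed integer seed driving all resampling.
#' @param nTest,nNull bootstrap draw counts (defaults 100 / 200).
#' @param minObservations minimum total observation filter (0 disables).
#' @param rescale estimate and apply a multiplicative group-B rescaling via
#'   [estimateGroupScaling()] (off by default).
#' @param icGate,alphaThreshold,betaThreshold,perGpThreshold,observedMode
#'   assessment thresholds; see [assessQuality()] and
#'   [rankGlycopeptides()].
#' @param outDir optional output directory; when given, writes
#'   `report.json`, `ranking.tsv`, `distributions.tsv` and the three plot
#'   types (`general_comparison.pdf`, `internal_similarity.pdf`,
#'   `abundance_pairs.pdf`).
#' @return list with `status` (one of `"differentiable"`,
#'   `"not_differentiable"`, `"quality_insufficient"`), `report`
#'   ([QualityReport-class]), `distributions`, `ranking`, `firstPass`
#'   (non-NULL when an outlier-removal rerun happened) and
#'   `removedReplicates`.
#' @export
runComparison <- function(a, b, seed = 1L, nTest = 100L, nNull = 200L,
                          minObservations = 2L, rescale = FALSE, icGate = 2,
                          alphaThreshold = 0.05, betaThreshold = 0.20,
                          perGpThreshold = 0.25,
                          observedMode = c("sd3", "central_quartile"),
                          outDir = NULL) {
  observedMode <- match.arg(observedMode)
  if (!isStandardized(a) || !isStandardized(b))
    stop("profiles must be standardized first (standardizeAbundances)",
         call. = FALSE)
  flt <- filterMinObservations(a, b, minObservations = minObservations,
                               enabled = minObservations > 0L)
  a <- flt$a; b <- flt$b
  if (rescale) b <- applyGroupScaling(b, estimateGroupScaling(a, b))
  pass1 <- .runOnce(a, b, nTest, nNull, seed, icGate, alphaThreshold,
                    betaThreshold, perGpThreshold, observedMode)
  dropA <- unique(pass1$report@outliersA$replicate[
    pass1$report@outliersA$removal_recommended])
  dropB <- unique(pass1$report@outliersB$replicate[
    pass1$report@outliersB$removal_recommended])
  firstPass <- NULL
  removed <- list(a = integer(0), b = integer(0))
  final <- pass1
  if (length(dropA) || length(dropB)) {
    a2 <- tryCatch(if (length(dropA)) .removeReplicates(a, dropA) else a,
                   error = function(e) NULL)
    b2 <- tryCatch(if (length(dropB)) .removeReplicates(b, dropB) else b,
                   error = function(e) NULL)
    if (!is.null(a2) && !is.null(b2)) {
      firstPass <- pass1
      removed <- list(a = dropA, b = dropB)
      final <- .runOnce(a2, b2, nTest, nNull, seed, icGate, alphaThreshold,
                        betaThreshold, perGpThreshold, observedMode)
    }
  }
  result <- list(status = final$report@status, report = final$report,
                 distributions = final$dist, ranking = final$ranking,
                 firstPass = firstPass, removedReplicates = removed,
                 profiles = if (is.null(firstPass)) list(a = a, b = b)
                            else list(a = a2, b = b2))
  if (!is.null(outDir)) .writeComparisonOutputs(result, outDir)
  result
}

.writeComparisonOutputs <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dist <- result$distributions
  payload <- .reportToList(result$report, dist, result$ranking)
  payload$removed_replicates <- result$removedReplicates
  if (!is.null(result$firstPass))
    payload$first_pass <- .reportToList(result$firstPass$report,
                                        result$firstPass$dist,
                                        result$firstPass$ranking)
  jsonlite::write_json(payload, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  writeRankingTable(result$ranking, file.path(outDir, "ranking.tsv"))
  writeDistributions(dist, file.path(outDir, "distributions.tsv"))
  grDevices::pdf(file.path(outDir, "general_comparison.pdf"), width = 7,
                 height = 5)
  plotGeneralComparison(dist, result$report)
  grDevices::dev.off()
  grDevices::pdf(file.path(outDir, "internal_similarity.pdf"), width = 10,
                 height = 5)
  op <- graphics::par(mfrow = c(1, 2))
  plotInternalSimilarity(dist, "A", result$report)
  plotInternalSimilarity(dist, "B", result$report)
  graphics::par(op)
  grDevices::dev.off()
  grDevices::pdf(file.path(outDir, "abundance_pairs.pdf"), width = 10,
                 height = 5)
  plotAbundancePairs(result$profiles$a, result$profiles$b)
  grDevices::dev.off()
  invisible(outDir)
}
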