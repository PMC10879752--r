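# Quality assessment: Internal Confidence, outlier replicates, observed
# validity, and the general Test-vs-Null differentiability decision.

#' Internal Confidence of a sample group
#'
#' An overlap-weighted z-type score of how far a group's Internal similarity
#' distribution sits above the Test distribution:
#' \deqn{IC = \frac{\mu_{Internal} - \mu_{Test}}{\sigma_{Internal}}
#'       \times 10^{-(\alpha+\beta)}}
#' with `alpha`/`beta` from [alphaBetaOverlap()] of the Test density against
#' the Internal density. An IC of 2 or more indicates the group coheres
#' distinctly better with itself than with the other group, i.e. the data
#' are of sufficient quality to support a comparison. The score is kept
#' signed: a negative IC means the group resembles the other group more than
#' itself (the samples may not be replicates), and both ICs near zero mean
#' all samples likely stem from one underlying glycosylation pattern.
#'
#' @param internal,test numeric similarity vectors (>= 2 values each).
#' @param overlap optional precomputed [OverlapResult-class]; when NULL it
#'   is computed from the kernel densities of the two vectors.
#' @return numeric IC, with the applied [OverlapResult-class] as attribute
#'   `"overlap"`.
#' @export
internalConfidence <- function(internal, test, overlap = NULL) {
  if (length(internal) < 2L || length(test) < 2L)
    stop("both distributions need at least 2 values", call. = FALSE)
  s <- stats::sd(internal)
  if (s < 1e-12) stop("degenerate internal distribution", call. = FALSE)
  if (is.null(overlap))
    overlap <- alphaBetaOverlap(estimateDensity(test), estimateDensity(internal))
  ic <- (mean(internal) - mean(test)) / s *
    10^(-(overlap@alpha + overlap@beta))
  attr(ic, "overlap") <- overlap
  ic
}

# Locate density peaks (local maxima) with a minimum prominence of 5% of the
# maximum density; returns peak indices and basin boundaries on the grid.
.densityPeaks <- function(grid, dens, prominenceFrac = 0.05) {
  n <- length(dens)
  left <- c(-Inf, dens[-n])
  right <- c(dens[-1L], -Inf)
  cand <- which(dens > left & dens >= right)
  if (!length(cand)) return(NULL)
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]; h <- dens[i]
    higherL <- cand[cand < i & dens[cand] > h]
    higherR <- cand[cand > i & dens[cand] > h]
    sadL <- if (length(higherL)) min(dens[max(higherL):i]) else -Inf
    sadR <- if (length(higherR)) min(dens[i:min(higherR)]) else -Inf
    prominence <- h - max(sadL, sadR, 0)
    if (!length(higherL) && !length(higherR)) prominence <- h
    keep[k] <- prominence >= prominenceFrac * max(dens)
  }
  peaks <- cand[keep]
  if (!length(peaks)) peaks <- cand[which.max(dens[cand])]
  # basin boundary between consecutive peaks = argmin of the valley
  bounds <- numeric(0)
  if (length(peaks) > 1L)
    bounds <- vapply(seq_len(length(peaks) - 1L), function(k) {
      seg <- peaks[k]:peaks[k + 1L]
      grid[seg[which.min(dens[seg])]]
    }, 0)
  list(peaks = peaks, boundaries = bounds)
}

#' Detect outlier replicates from the Internal distribution's modality
#'
#' A multimodal Internal similarity distribution indicates that comparisons
#' involving some replicate(s) behave systematically differently. Peaks of
#' the kernel density (local maxima with prominence at least 5% of the
#' maximum) partition the comparisons into basins; for every peak holding
#' more than 10% of the comparisons, each replicate's peak membership is the
#' proportion of in-peak comparisons whose two samplings contain that
#' replicate. Each replicate is z-scored against the leave-that-replicate-out
#' mean and SD of the others' membership proportions; to keep the z stable
#' when only a handful of replicates remain, the SD is floored at the
#' binomial standard error of the mean membership over the distinct
#' samplings appearing in the peak. |z| > 3 marks over- or
#' under-representation. The primary peak is the highest-similarity peak
#' above the mass gate: it represents the group's coherent core (with
#' replacement sampling at 3-4 replicates a degraded replicate enters the
#' majority of comparisons, so the largest-mass mode is typically the
#' contaminated one, not the reference behavior). Removal is recommended
#' only for a replicate under-represented in the primary peak or
#' over-represented in a non-primary peak. This machinery cannot separate
#' subgroups within a sample group; persistent multimodality after removal
#' indicates a deeper data-quality problem.
#'
#' @param values numeric Internal similarity values.
#' @param pairs integer matrix (2 x comparisons) of sampling indices.
#' @param samplings list of replicate-index multisets indexed by `pairs`.
#' @param nReplicates number of replicates in the group.
#' @param peakMassGate minimum fraction of comparisons a peak must hold
#'   (default 0.10).
#' @param zGate absolute z-score threshold (default 3).
#' @return list with `verdicts` (data.frame: replicate, peak, mass,
#'   membership, z, direction, removal_recommended), `unimodal` flag and the
#'   per-peak summary `peaks`.
#' @export
detectOutlierReplicates <- function(values, pairs, samplings, nReplicates,
                                    peakMassGate = 0.10, zGate = 3) {
  den <- estimateDensity(values)
  empty <- data.frame(replicate = integer(), peak = integer(), mass = numeric(),
                      membership = numeric(), z = numeric(),
                      direction = character(), removal_recommended = logical(),
                      stringsAsFactors = FALSE)
  if (den@degenerate)
    return(list(verdicts = empty, unimodal = TRUE,
                peaks = data.frame(peak = 1L, location = den@center, mass = 1)))
  pk <- .densityPeaks(den@grid, den@density)
  nPeaks <- length(pk$peaks)
  peakLoc <- den@grid[pk$peaks]
  if (nPeaks < 2L)
    return(list(verdicts = empty, unimodal = TRUE,
                peaks = data.frame(peak = 1L, location = peakLoc, mass = 1)))
  # assign comparisons to basins
  basin <- findInterval(values, pk$boundaries) + 1L
  mass <- tabulate(basin, nbins = nPeaks) / length(values)
  eligible <- which(mass > peakMassGate)
  if (!length(eligible))
    return(list(verdicts = empty, unimodal = FALSE,
                peaks = data.frame(peak = seq_len(nPeaks), location = peakLoc,
                                   mass = mass, primary = FALSE)))
  primary <- max(eligible)  # highest-similarity eligible peak: coherent core
  contains <- matrix(FALSE, nrow = length(values), ncol = nReplicates)
  inSampling <- vapply(samplings, function(s) tabulate(s, nReplicates) > 0L,
                       logical(nReplicates))           # nReplicates x samplings
  for (r in seq_len(nReplicates))
    contains[, r] <- inSampling[r, pairs[1L, ]] | inSampling[r, pairs[2L, ]]
  verdictList <- list()
  for (p in eligible) {
    inPeak <- basin == p
    memb <- colMeans(contains[inPeak, , drop = FALSE])
    kp <- length(unique(c(pairs[1L, inPeak], pairs[2L, inPeak])))
    for (r in seq_len(nReplicates)) {
      others <- memb[-r]
      mbar <- mean(others)
      se <- sqrt(max(mbar * (1 - mbar), 1e-6) / max(kp, 2L))
      z <- (memb[r] - mbar) / max(stats::sd(others), se)
      if (abs(z) <= zGate) next
      dir <- if (z > 0) "over" else "under"
      verdictList[[length(verdictList) + 1L]] <- data.frame(
        replicate = r, peak = p, mass = mass[p], membership = memb[r], z = z,
        direction = dir,
        removal_recommended = (dir == "under" && p == primary) ||
                              (dir == "over" && p != primary),
        stringsAsFactors = FALSE)
    }
  }
  verdicts <- if (length(verdictList)) do.call(rbind, verdictList) else empty
  list(verdicts = verdicts, unimodal = FALSE,
       peaks = data.frame(peak = seq_len(nPeaks), location = peakLoc,
                          mass = mass, primary = seq_len(nPeaks) == primary))
}

#' Validity of the Observed similarity against the Test distribution
#'
#' The bootstrap is considered to have simulated the original comparison
#' faithfully when the Observed similarity lies within 3 SD of the Test
#' distribution's mean (`mode = "sd3"`), or, under the stricter option,
#' within the central 50% of the Test distribution
#' (`mode = "central_quartile"`). Failure is more likely for highly similar
#' or very low-variability datasets.
#'
#' @param observed numeric scalar.
#' @param test numeric Test similarity values.
#' @param mode `"sd3"` or `"central_quartile"`.
#' @return list with `z` and `valid`.
#' @export
observedValidity <- function(observed, test,
                             mode = c("sd3", "central_quartile")) {
  mode <- match.arg(mode)
  s <- stats::sd(test)
  if (s < 1e-12)
    return(list(z = if (abs(observed - mean(test)) < 1e-12) 0 else Inf,
                valid = abs(observed - mean(test)) < 1e-12))
  z <- (observed - mean(test)) / s
  valid <- if (mode == "sd3") abs(z) <= 3
           else {
             q <- stats::quantile(test, c(0.25, 0.75), names = FALSE)
             observed >= q[1L] && observed <= q[2L]
           }
  list(z = z, valid = valid)
}

#' General Test-vs-Null comparison
#'
#' Computes the [alphaBetaOverlap()] of the Test density against the Null
#' density. The sample groups are declared differentiable in their overall
#' quantification patterns when `alpha < alphaThreshold` (FPR, conventional
#' 0.05) and `beta < betaThreshold` (FNR, conventional 0.20). A Null mean
#' below the Test mean is flagged as a sanity signal: it indicates very high
#' internal variability with low missingness.
#'
#' @param test,null numeric similarity vectors.
#' @param alphaThreshold,betaThreshold decision thresholds.
#' @return list with `overlap` ([OverlapResult-class]), `alpha`, `beta`,
#'   `differentiable` and `nullBelowTest`.
#' @export
generalComparison <- function(test, null, alphaThreshold = 0.05,
                              betaThreshold = 0.20) {
  ov <- alphaBetaOverlap(estimateDensity(test), estimateDensity(null))
  list(overlap = ov, alpha = ov@alpha, beta = ov@beta,
       differentiable = ov@alpha < alphaThreshold && ov@beta < betaThreshold,
       nullBelowTest = mean(null) < mean(test))
}

#' Full quality and differentiability assessment
#'
#' Turns a [SimilarityDistributions-class] into a [QualityReport-class]:
#' per-group Internal Confidence and Internal-vs-Test overlap, replicate
#' outlier verdicts, Observed-similarity validity, the Null-vs-Test sanity
#' flag, and the general differentiability decision.
#'
#' A group passes its quality gate when its IC reaches `icGate` and its
#' Internal-vs-Test overlap stays below the alpha/beta thresholds. The
#' overall status is `"not_differentiable"` when both ICs are close to zero
#' (all samples plausibly one glycosylation pattern) or when quality passes
#' but the general comparison finds no separation; `"quality_insufficient"`
#' when a group fails its gate outside that regime; `"differentiable"`
#' otherwise.
#'
#' @param dist a [SimilarityDistributions-class].
#' @param icGate minimum acceptable IC (default 2; raise for a more
#'   conservative analysis).
#' @param alphaThreshold,betaThreshold overlap thresholds (0.05 / 0.20).
#' @param observedMode passed to [observedValidity()].
#' @return A [QualityReport-class].
#' @export
assessQuality <- function(dist, icGate = 2, alphaThreshold = 0.05,
                          betaThreshold = 0.20,
                          observedMode = c("sd3", "central_quartile")) {
  observedMode <- match.arg(observedMode)
  narrative <- character()
  densTest <- estimateDensity(dist@test)
  icFor <- function(internal, label) {
    ov <- alphaBetaOverlap(densTest, estimateDensity(internal))
    ic <- as.numeric(internalConfidence(internal, dist@test, overlap = ov))
    if (ov@swapped)
      narrative <<- c(narrative, sprintf(
        "Internal distribution of %s sits below the Test distribution; overlap roles were swapped.", label))
    list(ic = ic, ov = ov)
  }
  qa <- icFor(dist@internalA, "group A")
  qb <- icFor(dist@internalB, "group B")
  outA <- detectOutlierReplicates(dist@internalA, dist@pairsInternalA,
                                  dist@collections$testA@samplings,
                                  dist@collections$testA@nReplicates)
  outB <- detectOutlierReplicates(dist@internalB, dist@pairsInternalB,
                                  dist@collections$testB@samplings,
                                  dist@collections$testB@nReplicates)
  obs <- observedValidity(dist@observed@value, dist@test, mode = observedMode)
  gen <- generalComparison(dist@test, dist@null, alphaThreshold, betaThreshold)
  passA <- qa$ic >= icGate && qa$ov@alpha < alphaThreshold &&
    qa$ov@beta < betaThreshold
  passB <- qb$ic >= icGate && qb$ov@alpha < alphaThreshold &&
    qb$ov@beta < betaThreshold
  if (!obs$valid)
    narrative <- c(narrative,
      sprintf("Observed similarity (z = %.2f) failed the %s validity gate: the bootstrap may not simulate the original comparison.",
              obs$z, observedMode))
  if (gen$nullBelowTest)
    narrative <- c(narrative,
      "Null mean is below the Test mean: very high internal variability with low missingness.")
  if (qa$ic < 0 || qb$ic < 0)
    narrative <- c(narrative,
      "A negative IC indicates a group less similar to itself than to the other group; the samples may not be replicates.")
  bothNearZero <- abs(qa$ic) < 1 && abs(qb$ic) < 1
  if (bothNearZero)
    narrative <- c(narrative,
      "Both ICs are close to zero: all samples likely stem from the same underlying glycosylation pattern.")
  nrecA <- sum(outA$verdicts$removal_recommended)
  nrecB <- sum(outB$verdicts$removal_recommended)
  if (nrecA + nrecB > 0)
    narrative <- c(narrative, sprintf(
      "Outlier detection recommends removing %d replicate(s) in group A and %d in group B.",
      length(unique(outA$verdicts$replicate[outA$verdicts$removal_recommended])),
      length(unique(outB$verdicts$replicate[outB$verdicts$removal_recommended]))))
  status <- if (bothNearZero && !gen$differentiable) "not_differentiable"
            else if (!passA || !passB) "quality_insufficient"
            else if (gen$differentiable) "differentiable"
            else "not_differentiable"
  methods::new("QualityReport",
               icA = qa$ic, icB = qb$ic, overlapA = qa$ov, overlapB = qb$ov,
               general = gen$overlap, observedZ = obs$z,
               observedValid = obs$valid, nullBelowTest = gen$nullBelowTest,
               outliersA = outA$verdicts, outliersB = outB$verdicts,
               differentiable = gen$differentiable,
               qualityPassA = passA, qualityPassB = passB,
               status = status, narrative = narrative,
               thresholds = list(ic_gate = icGate, alpha = alphaThreshold,
                                 beta = betaThreshold,
                                 observed_mode = observedMode))
}

setMethod("show", "QualityReport", function(object) {
  cat("QualityReport\n")
  cat(sprintf("  IC group A: %6.2f (FPR %.1f%%, FNR %.1f%%) quality %s\n",
              object@icA, 100 * object@overlapA@alpha,
              100 * object@overlapA@beta,
              if (object@qualityPassA) "PASS" else "FAIL"))
  cat(sprintf("  IC group B: %6.2f (FPR %.1f%%, FNR %.1f%%) quality %s\n",
              object@icB, 100 * object@overlapB@alpha,
              100 * object@overlapB@beta,
              if (object@qualityPassB) "PASS" else "FAIL"))
  cat(sprintf("  General:    FPR %.1f%%, FNR %.1f%% -> %sdifferentiable\n",
              100 * object@general@alpha, 100 * object@general@beta,
              if (object@differentiable) "" else "not "))
  cat(sprintf("  Observed z: %.2f (%s)\n", object@observedZ,
              if (object@observedValid) "valid" else "INVALID"))
  cat(sprintf("  Status: %s\n", object@status))
  for (msg in object@narrative) cat("  - ", msg, "\n", sep = "")
  invisible(NULL)
})
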