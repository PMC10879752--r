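# Contribution-based glycopeptide ranking with quality failure causes.

# alpha + beta overlap of two contribution samples after a joint rescale to
# [0, 1]. Distinct spikes are perfectly separated (0); identical samples are
# complete overlap (1).
.contributionOverlap <- function(internal, test) {
  rng <- range(c(internal, test))
  width <- diff(rng)
  if (width < 1e-12) return(1)
  xi <- (internal - rng[1L]) / width
  xt <- (test - rng[1L]) / width
  if (stats::sd(xi) < 1e-12 && stats::sd(xt) < 1e-12)
    return(if (abs(mean(xi) - mean(xt)) <= 1e-9) 1 else 0)
  ov <- alphaBetaOverlap(estimateDensity(xt), estimateDensity(xi))
  ov@alpha + ov@beta
}

#' Per-glycopeptide quality assessment from contribution distributions
#'
#' For each glycopeptide and each group, the overlap of the glycopeptide's
#' Internal contribution distribution with its Test contribution
#' distribution is computed as for the totaled distributions; because the
#' per-glycopeptide distributions are coarser, alpha and beta are combined
#' into a single threshold, and the group fails when `alpha + beta >=
#' combinedThreshold` (default 0.25). Failure causes, in precedence order:
#' never observed in a group (`UnseenIn_File1` / `UnseenIn_File2`), both
#' groups failing overlap (`LowQuality_Both`), a single side failing
#' (`LowQuality_File1` / `LowQuality_File2`), otherwise `Passed`.
#'
#' @param dist a [SimilarityDistributions-class].
#' @param combinedThreshold combined alpha+beta threshold (default 0.25).
#' @return data.frame with `glycopeptide`, `quality_pass`, `failure_cause`,
#'   `overlap_a`, `overlap_b`.
#' @export
assessGlycopeptideQuality <- function(dist, combinedThreshold = 0.25) {
  ids <- dist@ids
  presA <- dist@summaryA@presence
  presB <- dist@summaryB@presence
  n <- length(ids)
  ovA <- ovB <- rep(NA_real_, n)
  cause <- character(n)
  for (g in seq_len(n)) {
    if (presA[g] == 0 && presB[g] == 0) { cause[g] <- "AbsentEverywhere"; next }
    if (presA[g] == 0) { cause[g] <- "UnseenIn_File1"; next }
    if (presB[g] == 0) { cause[g] <- "UnseenIn_File2"; next }
    ovA[g] <- .contributionOverlap(dist@contribInternalA[g, ],
                                   dist@contribTest[g, ])
    ovB[g] <- .contributionOverlap(dist@contribInternalB[g, ],
                                   dist@contribTest[g, ])
    failA <- ovA[g] >= combinedThreshold
    failB <- ovB[g] >= combinedThreshold
    cause[g] <- if (failA && failB) "LowQuality_Both"
                else if (failA) "LowQuality_File1"
                else if (failB) "LowQuality_File2"
                else "Passed"
  }
  data.frame(glycopeptide = ids, quality_pass = cause == "Passed",
             failure_cause = cause, overlap_a = ovA, overlap_b = ovB,
             stringsAsFactors = FALSE)
}

#' Rank glycopeptides by their contribution to Test-vs-Null differentiation
#'
#' For every glycopeptide, each of its Test-comparison contributions (the
#' numerator term of the weighted Tanimoto) is z-scored against the mean and
#' SD of its Null contribution distribution; the ranking statistic is the
#' average of those z-scores. The lower (more negative) the z-score, the
#' higher the rank: the glycopeptide contributes less similarity in real
#' cross-group comparisons than chance resampling predicts. Glycopeptides
#' ideally driving differentiation score below -2, though missing values can
#' raise this; significantly positive z-scores may indicate an underlying
#' interdependence between the datasets. A degenerate (zero-SD) Null
#' contribution distribution is flagged `DegenerateNull` and z-scored
#' against a floor of 1e-9. Glycopeptides absent from both groups are
#' dropped, never ranked.
#'
#' @param dist a [SimilarityDistributions-class].
#' @param combinedThreshold per-glycopeptide quality threshold on
#'   alpha+beta (default 0.25), see [assessGlycopeptideQuality()].
#' @return data.frame sorted ascending by `z_score` (ties broken by id)
#'   with columns `glycopeptide`, `z_score`, `quality` ("T"/"F"),
#'   `quality_pass`, `likely_failure_cause`, `presence_a`, `presence_b`.
#' @export
rankGlycopeptides <- function(dist, combinedThreshold = 0.25) {
  ids <- dist@ids
  muN <- rowMeans(dist@contribNull)
  sdN <- apply(dist@contribNull, 1L, stats::sd)
  degenerate <- sdN < 1e-12
  z <- rowMeans((dist@contribTest - muN) / pmax(sdN, 1e-9))
  qual <- assessGlycopeptideQuality(dist, combinedThreshold)
  cause <- qual$failure_cause
  cause[degenerate & !cause %in% c("UnseenIn_File1", "UnseenIn_File2",
                                   "AbsentEverywhere")] <- "DegenerateNull"
  keep <- cause != "AbsentEverywhere"
  out <- data.frame(glycopeptide = ids,
                    z_score = z,
                    quality = ifelse(cause == "Passed", "T", "F"),
                    quality_pass = cause == "Passed",
                    likely_failure_cause = cause,
                    presence_a = dist@summaryA@presence,
                    presence_b = dist@summaryB@presence,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(out$z_score, out$glycopeptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a ranking table to TSV
#'
#' Columns mirror the reporting format: glycopeptide, z_score, quality
#' (T/F), likely_failure_cause, presence_a, presence_b.
#'
#' @param ranking data.frame from [rankGlycopeptides()].
#' @param file output path.
#' @export
writeRankingTable <- function(ranking, file) {
  cols <- c("glycopeptide", "z_score", "quality", "likely_failure_cause",
            "presence_a", "presence_b")
  utils::write.table(ranking[, cols], file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
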