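#' Summarize a dataset over a (bootstrap) replicate selection
#'
#' Computes, for every glycopeptide, the mean of its nonzero standardized
#' abundances over the selected replicates and the fraction of those
#' replicates in which it was observed. The selection is a multiset: in a
#' bootstrap draw a repeated replicate counts with its multiplicity in both
#' the mean and the presence fraction. Zeros are excluded from the mean
#' because missingness is already penalized through the presence term;
#' averaging zeros in would double-penalize.
#'
#' @param x standardized [GlycoProfile-class].
#' @param selection integer vector of replicate indices (repeats allowed);
#'   defaults to all replicates once.
#' @return A [DatasetSummary-class].
#' @examples
#' m <- matrix(c(2, 0, 4), nrow = 1,
#'             dimnames = list("PEPA{3;2;0;0;0}", c("r1", "r2", "r3")))
#' p <- glycoProfile(m, standardized = TRUE)
#' summarizeDataset(p)                 # mean 3, presence 2/3
#' summarizeDataset(p, c(2, 2, 2))     # all-missing selection: mean 0
#' @export
summarizeDataset <- function(x, selection = seq_len(ncol(x))) {
  m <- abundanceMatrix(x)
  if (length(selection) == 0L) stop("empty replicate selection", call. = FALSE)
  if (any(selection < 1L | selection > ncol(m)))
    stop("replicate selection index out of range", call. = FALSE)
  v <- m[, selection, drop = FALSE]
  cnt <- rowSums(v > 0)
  methods::new("DatasetSummary",
               ids = rownames(m),
               meanAbundance = as.numeric(ifelse(cnt > 0, rowSums(v) / pmax(cnt, 1L), 0)),
               presence = as.numeric(cnt / length(selection)),
               nReplicates = length(selection))
}

# Vectorized similarity over paired summary matrices (glycopeptide x pairs).
# Returns the values, the per-glycopeptide numerator terms and denominators.
# The distance weight K^(-d) is computed in log space; underflow clamps to 0.
.pairSimilarity <- function(mA, pA, mB, pB) {
  wA <- mA * pA
  wB <- mB * pB
  K <- 1 + (pA + pB) / 2
  d <- abs(mA - mB)
  num <- wA * wB * exp(-d * log(K))
  sn <- colSums(num)
  den <- colSums(wA * wA) + colSums(wB * wB) - sn
  value <- ifelse(den > 0, sn / den, 1)
  list(value = pmin(pmax(value, 0), 1), num = num, den = den)
}

#' Original (unweighted) Tanimoto similarity
#'
#' The classical continuous Tanimoto over the two mean-abundance vectors:
#' \deqn{T = \frac{\sum_i A_i B_i}{\sum_i A_i^2 + \sum_i B_i^2 - \sum_i A_i B_i}}
#' Presence is ignored. Two all-zero summaries compare as 1 (identical
#' emptiness) with a warning.
#'
#' @param a,b [DatasetSummary-class] objects with aligned ids.
#' @return numeric scalar in \[0,1\].
#' @export
tanimotoOriginal <- function(a, b) {
  .assertAligned(a@ids, b@ids)
  A <- a@meanAbundance; B <- b@meanAbundance
  num <- sum(A * B)
  den <- sum(A^2) + sum(B^2) - num
  if (den <= 0) {
    warning("both summaries are all-zero; similarity defined as 1")
    return(1)
  }
  num / den
}

#' Presence- and distance-weighted Tanimoto similarity
#'
#' The core metric. Per glycopeptide `i` with mean abundances `A_i`, `B_i`
#' and presence rates `P_iA`, `P_iB`:
#' \deqn{K_i = 1 + (P_{iA} + P_{iB})/2, \quad d_i = |A_i - B_i|}
#' \deqn{T = \frac{\sum_i A_i P_{iA} B_i P_{iB} K_i^{-d_i}}
#'                {\sum_i (A_i P_{iA})^2 + \sum_i (B_i P_{iB})^2 -
#'                 \sum_i A_i P_{iA} B_i P_{iB} K_i^{-d_i}}}
#' The presence weights let missingness depress within-group (Internal)
#' similarity, enforcing conservative data-quality assessment; the distance
#' term down-weights glycopeptides whose group abundances differ, and does so
#' more strongly the better they are observed. The value always lies in
#' \[0,1\] (the numerator is bounded by the geometric mean of the self
#' terms). Two all-zero summaries compare as 1 with `bothEmpty = TRUE` and a
#' warning.
#'
#' @param a,b [DatasetSummary-class] objects with aligned ids.
#' @param kMode `"per_glycopeptide"` (default) computes `K_i` from the two
#'   presence rates of glycopeptide `i`; `"global"` uses one `K` equal to one
#'   plus the grand mean presence rate of both summaries.
#' @return A [SimilarityResult-class].
#' @examples
#' s <- function(A, P) methods::new("DatasetSummary", ids = "PEPA{3;2;0;0;0}",
#'   meanAbundance = A, presence = P, nReplicates = 2L)
#' tanimotoModified(s(2, 1), s(1, 1))@value   # 0.25
#' @export
tanimotoModified <- function(a, b, kMode = c("per_glycopeptide", "global")) {
  kMode <- match.arg(kMode)
  .assertAligned(a@ids, b@ids)
  A <- a@meanAbundance; PA <- a@presence
  B <- b@meanAbundance; PB <- b@presence
  K <- if (kMode == "global") rep(1 + mean(c(PA, PB)), length(A))
       else 1 + (PA + PB) / 2
  d <- abs(A - B)
  num <- A * PA * B * PB * exp(-d * log(K))
  sa <- (A * PA)^2
  sb <- (B * PB)^2
  den <- sum(sa) + sum(sb) - sum(num)
  bothEmpty <- den <= 0
  if (bothEmpty) warning("both summaries are all-zero; similarity defined as 1")
  value <- if (bothEmpty) 1 else min(max(sum(num) / den, 0), 1)
  methods::new("SimilarityResult", ids = a@ids, value = value,
               numeratorTerms = num, selfTermsA = sa, selfTermsB = sb,
               bothEmpty = bothEmpty)
}

#' Per-glycopeptide contribution terms of a similarity comparison
#'
#' Returns the raw numerator terms of the weighted Tanimoto, without
#' denominator normalization: missing values bias the shared denominator
#' (and do so more in Null-type resamplings), which would mask exactly the
#' missingness-driven contributors the ranking step needs to surface.
#'
#' @param result a [SimilarityResult-class].
#' @return named numeric vector of contributions (>= 0).
#' @export
contributionTerms <- function(result) {
  stats::setNames(result@numeratorTerms, result@ids)
}

setMethod("show", "SimilarityResult", function(object) {
  cat(sprintf("SimilarityResult: value %.4f over %d glycopeptides%s\n",
              object@value, length(object@ids),
              if (object@bothEmpty) " (both empty)" else ""))
  invisible(NULL)
})
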