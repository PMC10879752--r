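#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' GlycoProfile: a glycopeptide-by-replicate abundance matrix
#'
#' Container for one sample group of a glycosite-level quantification
#' experiment. Rows are glycopeptide identifications (peptide backbone plus
#' glycan composition), columns are LC-MS replicates. Values are nonnegative
#' abundances; an exact zero encodes "not observed" (missing), never a
#' measured zero. The parsed glycan composition (Hex, HexNAc, Fuc, NeuAc,
#' Sulfate) is kept in `rowData`, the optional per-replicate total ion
#' current in `colData$tic`.
#'
#' @slot ... inherits all slots from
#'   [SummarizedExperiment::SummarizedExperiment-class]; the single assay is
#'   named `"abundance"`. `metadata()` carries `group_label`, `standardized`
#'   and `log_base`.
#'
#' @seealso [glycoProfile()], [readAbundanceTable()], [standardizeAbundances()]
#' @export
setClass("GlycoProfile", contains = "SummarizedExperiment")

setValidity("GlycoProfile", function(object) {
  msg <- character()
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  else {
    m <- SummarizedExperiment::assay(object, "abundance")
    if (anyNA(m)) msg <- c(msg, "abundance values must not be NA (use 0 for missing)")
    else if (any(m < 0)) msg <- c(msg, "abundance values must be >= 0")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "glycopeptide ids must be unique after canonicalization")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "replicate names must be unique")
  tic <- object$tic
  if (!is.null(tic) && any(!is.na(tic) & tic <= 0))
    msg <- c(msg, "TIC values must be positive")
  if (length(msg)) msg else TRUE
})

#' DatasetSummary: per-glycopeptide mean abundance and presence
#'
#' Summary of one (possibly bootstrap-resampled) dataset: for every
#' glycopeptide, the mean of its nonzero standardized abundances over the
#' selected replicates and the fraction of those replicates in which it was
#' observed. Repeated replicates in a bootstrap selection count with their
#' multiplicity.
#'
#' @slot ids character, canonical glycopeptide identifiers.
#' @slot meanAbundance numeric, mean of nonzero values (0 if never observed).
#' @slot presence numeric in \[0,1\], fraction of replicates observed.
#' @slot nReplicates integer, size of the replicate selection.
#' @export
setClass("DatasetSummary",
  representation(ids = "character", meanAbundance = "numeric",
                 presence = "numeric", nReplicates = "integer"))

setValidity("DatasetSummary", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (length(object@meanAbundance) != n || length(object@presence) != n)
    msg <- c(msg, "ids, meanAbundance and presence must be the same length")
  if (any(object@presence < 0 | object@presence > 1))
    msg <- c(msg, "presence must lie in [0, 1]")
  if (any((object@presence == 0) != (object@meanAbundance == 0)))
    msg <- c(msg, "presence == 0 must hold exactly when meanAbundance == 0")
  frac <- object@presence * object@nReplicates
  if (any(abs(frac - round(frac)) > 1e-9))
    msg <- c(msg, "presence * nReplicates must be an integer")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SimilarityResult: one weighted Tanimoto value with its decomposition
#'
#' The similarity value together with the per-glycopeptide numerator terms
#' (the "contributions") and the two self-similarity terms that make up the
#' denominator.
#'
#' @slot ids character.
#' @slot value numeric scalar in \[0,1\].
#' @slot numeratorTerms numeric, per-glycopeptide
#'   \eqn{A_i P_{i,A} B_i P_{i,B} K_i^{-d_i}}.
#' @slot selfTermsA,selfTermsB numeric, \eqn{(A_i P_{i,A})^2} and
#'   \eqn{(B_i P_{i,B})^2}.
#' @slot bothEmpty logical, TRUE when both summaries were all-zero and the
#'   value 1 was assigned by convention (identical emptiness).
#' @export
setClass("SimilarityResult",
  representation(ids = "character", value = "numeric",
                 numeratorTerms = "numeric", selfTermsA = "numeric",
                 selfTermsB = "numeric", bothEmpty = "logical"))

setValidity("SimilarityResult", function(object) {
  msg <- character()
  if (length(object@value) != 1L) msg <- c(msg, "value must be a scalar")
  else if (object@value < -1e-12 || object@value > 1 + 1e-12)
    msg <- c(msg, "value must lie in [0, 1]")
  if (any(object@numeratorTerms < -1e-12))
    msg <- c(msg, "numerator terms must be >= 0")
  den <- sum(object@selfTermsA) + sum(object@selfTermsB) - sum(object@numeratorTerms)
  if (den > 1e-12 &&
      abs(object@value - sum(object@numeratorTerms) / den) > 1e-8)
    msg <- c(msg, "value must equal sum(numerator) / (selfA + selfB - numerator)")
  if (length(msg)) msg else TRUE
})

#' SamplingCollection: deduplicated bootstrap samplings of one source
#'
#' A collection of replicate-index multisets drawn with replacement from a
#' source table (one sample group, or the pooled groups for the null), with
#' the per-sampling dataset summaries cached as matrices for fast pairwise
#' similarity evaluation. Samplings are canonicalized as sorted index tuples
#' and deduplicated.
#'
#' @slot sourceLabel character scalar.
#' @slot samplings list of sorted integer vectors (multisets of replicate
#'   indices into the source table).
#' @slot means,presence numeric matrices, glycopeptide x sampling.
#' @slot ids character, row identifiers shared by the matrices.
#' @slot nReplicates integer, the size every sampling must have.
#' @export
setClass("SamplingCollection",
  representation(sourceLabel = "character", samplings = "list",
                 means = "matrix", presence = "matrix",
                 ids = "character", nReplicates = "integer"))

setValidity("SamplingCollection", function(object) {
  msg <- character()
  key <- vapply(object@samplings, function(s) paste(s, collapse = ","), "")
  if (anyDuplicated(key)) msg <- c(msg, "samplings must be distinct multisets")
  sizes <- lengths(object@samplings)
  if (length(sizes) && any(sizes != object@nReplicates))
    msg <- c(msg, "every sampling must have the source replicate count")
  if (ncol(object@means) != length(object@samplings) ||
      ncol(object@presence) != length(object@samplings))
    msg <- c(msg, "summary matrices must have one column per sampling")
  if (length(msg)) msg else TRUE
})

#' SimilarityDistributions: the four contextual similarity distributions
#'
#' Holds the Internal (per group), Test and Null similarity distributions,
#' the Observed (unsampled) similarity, the sampling-pair identity of every
#' comparison, and the per-comparison per-glycopeptide contribution records
#' needed by the ranking step.
#'
#' @slot internalA,internalB,test,null numeric similarity values in \[0,1\].
#' @slot pairsInternalA,pairsInternalB,pairsTest,pairsNull integer matrices
#'   (2 x comparisons) of sampling indices into the respective collections.
#' @slot contribInternalA,contribInternalB,contribTest,contribNull numeric
#'   matrices (glycopeptide x comparisons) of numerator terms.
#' @slot observed [SimilarityResult-class] for the unsampled comparison.
#' @slot summaryA,summaryB [DatasetSummary-class] of the full groups.
#' @slot collections list with elements `testA`, `testB`, `nullA`, `nullB`
#'   ([SamplingCollection-class]).
#' @slot ids character; \code{seed} integer used for all resampling.
#' @export
setClass("SimilarityDistributions",
  representation(internalA = "numeric", internalB = "numeric",
                 test = "numeric", null = "numeric",
                 pairsInternalA = "matrix", pairsInternalB = "matrix",
                 pairsTest = "matrix", pairsNull = "matrix",
                 contribInternalA = "matrix", contribInternalB = "matrix",
                 contribTest = "matrix", contribNull = "matrix",
                 observed = "SimilarityResult",
                 summaryA = "DatasetSummary", summaryB = "DatasetSummary",
                 collections = "list", ids = "character", seed = "integer"))

setValidity("SimilarityDistributions", function(object) {
  msg <- character()
  vals <- c(object@internalA, object@internalB, object@test, object@null)
  if (any(vals < -1e-9 | vals > 1 + 1e-9))
    msg <- c(msg, "all similarity values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' DensityEstimate: a kernel density restricted to the unit interval
#'
#' Gaussian-kernel density on a fixed 512-point grid over \[-0.05, 1.05\],
#' clipped to \[0, 1\] and renormalized so the trapezoid integral is 1.
#' Bandwidth is Silverman's rule with a floor of 1e-3; a sample with no
#' spread is flagged `degenerate` and represented as a narrow Gaussian spike
#' so that downstream overlap machinery remains defined.
#'
#' @slot grid,density numeric vectors; \code{bandwidth} numeric scalar.
#' @slot degenerate logical; \code{center} numeric, the sample mean.
#' @export
setClass("DensityEstimate",
  representation(grid = "numeric", density = "numeric",
                 bandwidth = "numeric", degenerate = "logical",
                 center = "numeric"))

setValidity("DensityEstimate", function(object) {
  if (length(object@grid) != length(object@density))
    return("grid and density must be the same length")
  if (is.unsorted(object@grid, strictly = TRUE))
    return("grid must be strictly increasing")
  if (any(object@density < 0)) return("density must be nonnegative")
  int <- .trapz(object@grid, object@density)
  if (abs(int - 1) > 1e-6)
    return(sprintf("density must integrate to 1 (got %.8f)", int))
  TRUE
})

#' OverlapResult: density-overlap false positive and false negative rates
#'
#' @slot alpha,beta numeric in \[0,1\]: the FPR and FNR read off the
#'   overlap of a Test density with a reference density.
#' @slot crossing numeric, the point x at which the Test density first drops
#'   below the reference between the two distribution means.
#' @slot swapped logical, TRUE when the nominal reference had the lower mean
#'   and the roles were exchanged before integrating.
#' @export
setClass("OverlapResult",
  representation(alpha = "numeric", beta = "numeric",
                 crossing = "numeric", swapped = "logical"))

setValidity("OverlapResult", function(object) {
  if (object@alpha < -1e-9 || object@alpha > 1 + 1e-9) return("alpha must lie in [0,1]")
  if (object@beta < -1e-9 || object@beta > 1 + 1e-9) return("beta must lie in [0,1]")
  TRUE
})

#' QualityReport: the full data-quality and differentiability assessment
#'
#' @slot icA,icB numeric Internal Confidence scores (signed).
#' @slot overlapA,overlapB [OverlapResult-class], Internal-vs-Test per group.
#' @slot general [OverlapResult-class], Test-vs-Null.
#' @slot observedZ numeric; \code{observedValid} logical.
#' @slot nullBelowTest logical sanity flag (mean Null below mean Test).
#' @slot outliersA,outliersB per-replicate verdict data frames from
#'   [detectOutlierReplicates()].
#' @slot differentiable logical: general alpha and beta below thresholds.
#' @slot qualityPassA,qualityPassB logical per-group quality gates.
#' @slot status character, one of `"differentiable"`,
#'   `"not_differentiable"`, `"quality_insufficient"`.
#' @slot narrative character, triggered rule messages.
#' @slot thresholds list of the thresholds that were applied.
#' @export
setClass("QualityReport",
  representation(icA = "numeric", icB = "numeric",
                 overlapA = "OverlapResult", overlapB = "OverlapResult",
                 general = "OverlapResult",
                 observedZ = "numeric", observedValid = "logical",
                 nullBelowTest = "logical",
                 outliersA = "data.frame", outliersB = "data.frame",
                 differentiable = "logical",
                 qualityPassA = "logical", qualityPassB = "logical",
                 status = "character",
                 narrative = "character", thresholds = "list"))
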