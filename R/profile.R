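#' Construct a GlycoProfile
#'
#' @param values numeric matrix, glycopeptides x replicates, nonnegative;
#'   exact zeros encode missing observations. Row names must be glycopeptide
#'   identifiers in the `PEP{Hex;HexNAc;Fuc;NeuAc;Sulfate}` grammar; column
#'   names are replicate names.
#' @param group character scalar label for the sample group.
#' @param tic optional numeric vector of per-replicate total ion currents
#'   (positive), recycled against the columns by name or position.
#' @param standardized logical; TRUE when `values` are already standardized
#'   log abundances (as emitted by [simulateScenario()]), FALSE for raw ion
#'   intensities that still need [standardizeAbundances()].
#' @param logBase base recorded for standardized values.
#' @return A [GlycoProfile-class].
#' @examples
#' m <- matrix(c(5, 0, 7, 6, 4, 0), nrow = 3,
#'             dimnames = list(c("PEPA{3;2;0;0;0}", "PEPA{4;2;1;0;0}",
#'                               "PEPB{5;4;0;1;0}"), c("r1", "r2")))
#' glycoProfile(m, group = "control", standardized = TRUE)
#' @export
glycoProfile <- function(values, group = "group", tic = NULL,
                         standardized = FALSE, logBase = 10) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry glycopeptide row names and replicate column names",
         call. = FALSE)
  comp <- parseGlycopeptide(rownames(values))
  rownames(values) <- glycopeptideString(comp)  # canonical form
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  if (!is.null(tic)) {
    if (!is.null(names(tic))) tic <- tic[colnames(values)]
    if (length(tic) != ncol(values))
      stop("tic must supply one value per replicate", call. = FALSE)
    cd$tic <- as.numeric(tic)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values),
    rowData = S4Vectors::DataFrame(comp, row.names = rownames(values)),
    colData = cd)
  obj <- methods::new("GlycoProfile", se)
  S4Vectors::metadata(obj)$group_label <- as.character(group)
  S4Vectors::metadata(obj)$standardized <- isTRUE(standardized)
  S4Vectors::metadata(obj)$log_base <- logBase
  methods::validObject(obj)
  obj
}

#' @describeIn glycoProfile the abundance matrix.
#' @param x a `GlycoProfile`.
#' @export
abundanceMatrix <- function(x) SummarizedExperiment::assay(x, "abundance")

#' @describeIn glycoProfile the sample-group label.
#' @export
groupLabel <- function(x) S4Vectors::metadata(x)$group_label

#' @describeIn glycoProfile TRUE when values are standardized log abundances.
#' @export
isStandardized <- function(x) isTRUE(S4Vectors::metadata(x)$standardized)

#' @describeIn glycoProfile per-replicate TIC values, or NULL.
#' @export
ticValues <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("tic" %in% colnames(cd)) stats::setNames(cd$tic, rownames(cd)) else NULL
}

#' @describeIn glycoProfile parsed glycopeptide compositions (`data.frame`).
#' @export
glycopeptideTable <- function(x)
  as.data.frame(SummarizedExperiment::rowData(x))

setMethod("show", "GlycoProfile", function(object) {
  m <- abundanceMatrix(object)
  cat(sprintf("GlycoProfile '%s': %d glycopeptides x %d replicates (%s)\n",
              groupLabel(object), nrow(m), ncol(m),
              if (isStandardized(object)) "standardized log abundance"
              else "raw intensity"))
  obs <- mean(m > 0)
  cat(sprintf("  overall presence rate: %.1f%%; TIC: %s\n", 100 * obs,
              if (is.null(ticValues(object))) "absent" else "present"))
  invisible(NULL)
})
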