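#' Read a glycopeptide abundance table
#'
#' Reads a delimited text file whose header row holds replicate names, whose
#' first column holds glycopeptide identifiers in the
#' `PEP{Hex;HexNAc;Fuc;NeuAc;Sulfate}` grammar, and whose body holds
#' nonnegative raw ion abundances (AUCs). Blank and `NA` cells are coerced to
#' 0, the missing-value code. Rows that share an identifier after
#' canonicalization are merged by summation before any log transform
#' (signal split across charge states or adducts).
#'
#' @param file path to a TSV or CSV file (separator chosen from the
#'   extension, tab otherwise).
#' @param group sample-group label; defaults to the file name.
#' @param tic optional named numeric vector of per-replicate TICs, or the
#'   path to a two-column sidecar TSV (`replicate_name`, `tic`).
#' @param sep field separator; overrides the extension heuristic.
#' @return A raw-scale [GlycoProfile-class].
#' @export
readAbundanceTable <- function(file, group = basename(file), tic = NULL,
                               sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(file, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (nrow(df) == 0L) stop("no glycopeptide rows in '", file, "'", call. = FALSE)
  reps <- colnames(df)[-1L]
  if (anyDuplicated(reps))
    stop("duplicate replicate names in '", file, "': ",
         paste(unique(reps[duplicated(reps)]), collapse = ", "), call. = FALSE)
  ids <- as.character(df[[1L]])
  body <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(body) <- "double"
  body[is.na(body)] <- 0
  if (any(body < 0))
    stop("negative abundance values are not allowed", call. = FALSE)
  ids <- glycopeptideString(parseGlycopeptide(ids))
  if (anyDuplicated(ids)) {
    body <- rowsum(body, group = ids, reorder = FALSE)
    ids <- rownames(body)
  }
  rownames(body) <- ids
  if (is.character(tic) && length(tic) == 1L) {
    tt <- utils::read.table(tic, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    tic <- stats::setNames(as.numeric(tt[[2L]]), as.character(tt[[1L]]))
  }
  glycoProfile(body, group = group, tic = tic, standardized = FALSE)
}

#' Write a GlycoProfile back to TSV
#'
#' Round-trippable inverse of [readAbundanceTable()] (for standardized
#' tables, of the generator output): first column `glycopeptide`, remaining
#' columns the replicates.
#'
#' @param x a [GlycoProfile-class].
#' @param file output path.
#' @export
writeAbundanceTable <- function(x, file) {
  m <- abundanceMatrix(x)
  df <- data.frame(glycopeptide = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Standardize raw abundances to relative log scale
#'
#' Nonzero cells become `log(value, logBase)`; zeros stay zero (still
#' missing). With `useTic = TRUE` every replicate column is additionally
#' divided by `log(TIC, logBase)` of that replicate, scaling signal strength
#' in proportion to the log of the total ion current while keeping values
#' dimensionless and order-preserving.
#'
#' Raw values in (0, 1] are rejected rather than clipped: their logs would be
#' nonpositive and break the sign contract of the similarity numerator.
#' Supply raw ion intensities (typically much greater than 1).
#'
#' @param x raw-scale [GlycoProfile-class].
#' @param logBase log base (> 1), default 10.
#' @param useTic divide each column by the log TIC of its replicate.
#' @return A standardized [GlycoProfile-class] with the same zero pattern.
#' @export
standardizeAbundances <- function(x, logBase = 10, useTic = FALSE) {
  if (logBase <= 1) stop("logBase must be > 1", call. = FALSE)
  if (isStandardized(x)) {
    warning("profile is already standardized; returning unchanged")
    return(x)
  }
  m <- abundanceMatrix(x)
  if (any(m > 0 & m <= 1))
    stop("raw values in (0, 1] would produce nonpositive log abundances; ",
         "pre-scale the data or supply raw ion intensities (>> 1)",
         call. = FALSE)
  out <- m
  nz <- m > 0
  out[nz] <- log(m[nz], base = logBase)
  if (useTic) {
    tic <- ticValues(x)
    if (is.null(tic)) stop("useTic = TRUE but no TIC values present", call. = FALSE)
    if (any(tic <= 1)) stop("TIC values must be > 1 for log scaling", call. = FALSE)
    out <- sweep(out, 2L, log(tic, base = logBase), "/")
  }
  glycoProfile(out, group = groupLabel(x), tic = ticValues(x),
               standardized = TRUE, logBase = logBase)
}

#' Align two groups and filter on minimum total observations
#'
#' The glycopeptide universes of the two groups are unioned first (rows
#' missing from one group are added as all-zero), then identifications whose
#' total nonzero observation count across both groups falls below
#' `minObservations` are removed from both. The outputs always share an
#' identical identifier list in identical order, as required by the
#' similarity metric's common index.
#'
#' @param a,b standardized [GlycoProfile-class] objects.
#' @param minObservations nonnegative integer; 0 (or `enabled = FALSE`)
#'   disables the filter and only aligns.
#' @param enabled logical master switch for the filter.
#' @return list with elements `a` and `b`, aligned profiles.
#' @export
filterMinObservations <- function(a, b, minObservations = 2L, enabled = TRUE) {
  ma <- abundanceMatrix(a); mb <- abundanceMatrix(b)
  ids <- union(rownames(ma), rownames(mb))
  fill <- function(m) {
    out <- matrix(0, nrow = length(ids), ncol = ncol(m),
                  dimnames = list(ids, colnames(m)))
    out[rownames(m), ] <- m
    out
  }
  ma <- fill(ma); mb <- fill(mb)
  if (enabled && minObservations > 0L) {
    if (minObservations > ncol(ma) + ncol(mb))
      stop("minObservations exceeds the total replicate count", call. = FALSE)
    keep <- rowSums(ma > 0) + rowSums(mb > 0) >= minObservations
    if (!any(keep))
      stop("no glycopeptides survive filtering", call. = FALSE)
    ma <- ma[keep, , drop = FALSE]; mb <- mb[keep, , drop = FALSE]
  }
  list(a = glycoProfile(ma, group = groupLabel(a), tic = ticValues(a),
                        standardized = isStandardized(a)),
       b = glycoProfile(mb, group = groupLabel(b), tic = ticValues(b),
                        standardized = isStandardized(b)))
}

#' Estimate a multiplicative between-group rescaling factor
#'
#' Estimates the factor `s` that best maps group B onto group A via a
#' through-origin linear fit of the per-glycopeptide mean nonzero abundances
#' over glycopeptides observed at least once in both groups:
#' `s = sum(a * b) / sum(b^2)`. Useful when a semi-uniform abundance shift is
#' not captured by TIC standardization. Rescaling is deliberately not applied
#' automatically; see [applyGroupScaling()].
#'
#' @param a,b standardized, aligned [GlycoProfile-class] objects.
#' @return positive numeric scalar `s`.
#' @export
estimateGroupScaling <- function(a, b) {
  ma <- abundanceMatrix(a); mb <- abundanceMatrix(b)
  .assertAligned(rownames(ma), rownames(mb), "profiles")
  meanNZ <- function(m) {
    cnt <- rowSums(m > 0)
    ifelse(cnt > 0, rowSums(m) / pmax(cnt, 1L), 0)
  }
  x <- meanNZ(ma); y <- meanNZ(mb)
  co <- x > 0 & y > 0
  if (sum(co) < 3L)
    stop("fewer than 3 co-observed glycopeptides; rescaling unavailable",
         call. = FALSE)
  sum(x[co] * y[co]) / sum(y[co]^2)
}

#' Apply a multiplicative rescaling to group B
#'
#' Multiplies the nonzero cells of `b` by `s`; zeros (missing values) are
#' untouched, so the missingness pattern is conserved. The operation is
#' logged loudly because rescaling is a manual, interpretive step.
#'
#' @param b standardized [GlycoProfile-class].
#' @param s positive scaling factor, e.g. from [estimateGroupScaling()].
#' @return the rescaled profile.
#' @export
applyGroupScaling <- function(b, s) {
  stopifnot(is.numeric(s), length(s) == 1L, s > 0)
  message(sprintf("applying multiplicative group rescaling s = %.4f to '%s'",
                  s, groupLabel(b)))
  m <- abundanceMatrix(b)
  m[m > 0] <- m[m > 0] * s
  glycoProfile(m, group = groupLabel(b), tic = ticValues(b),
               standardized = isStandardized(b))
}
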