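# Internal numeric helpers.

# Trapezoid integral of y over x.
.trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

# Evaluate code under a fixed RNG state, restoring the caller's stream.
.withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Canonical key of a replicate-index multiset.
.samplingKey <- function(idx) paste(idx, collapse = ",")

.assertAligned <- function(idsA, idsB, what = "summaries") {
  if (length(idsA) != length(idsB) || any(idsA != idsB))
    stop("glycopeptide ids of the two ", what, " are not aligned; ",
         "run filterMinObservations() first", call. = FALSE)
  invisible(TRUE)
}
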