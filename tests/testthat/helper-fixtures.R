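# Shared fixture builders and independent oracles.

# A standardized profile from a bare matrix; ids generated in the grammar.
makeProfile <- function(values, group = "g", ids = NULL, reps = NULL) {
  values <- as.matrix(values)
  if (is.null(ids))
    ids <- sprintf("PEP{%d;2;0;0;0}", seq_len(nrow(values)) + 2L)
  if (is.null(reps)) reps <- paste0(group, "_r", seq_len(ncol(values)))
  dimnames(values) <- list(ids, reps)
  glycoProfile(values, group = group, standardized = TRUE)
}

makeSummary <- function(A, P, n = 2L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("PEP{%d;2;0;0;0}", seq_along(A) + 2L)
  methods::new("DatasetSummary", ids = ids, meanAbundance = as.numeric(A),
               presence = as.numeric(P), nReplicates = as.integer(n))
}

# Independent direct transcription of the weighted Tanimoto definition:
# a plain element-by-element loop, kept free of the package's vectorized path.
tmodOracle <- function(A, PA, B, PB) {
  num <- 0
  for (i in seq_along(A)) {
    K <- 1 + (PA[i] + PB[i]) / 2
    d <- abs(A[i] - B[i])
    num <- num + A[i] * PA[i] * B[i] * PB[i] * K^(-d)
  }
  den <- sum((A * PA)^2) + sum((B * PB)^2) - num
  if (den <= 0) 1 else num / den
}

# Random valid summary pair on <= maxGp glycopeptides (presence on a
# replicate grid so the validity contract holds).
randomSummaryPair <- function(maxGp = 5L, nRep = 4L) {
  n <- sample.int(maxGp, 1L)
  ids <- sprintf("PEP{%d;2;0;0;0}", seq_len(n) + 2L)
  draw <- function() {
    cnt <- sample(0:nRep, n, replace = TRUE)
    if (all(cnt == 0)) cnt[1L] <- 1L
    A <- ifelse(cnt > 0, stats::runif(n, 0.5, 8), 0)
    makeSummary(A, cnt / nRep, nRep, ids)
  }
  list(a = draw(), b = draw())
}

# Enumerate all distinct multisets of size k from n elements (oracle for
# duplicate-reduction ceilings).
enumerateMultisets <- function(n, k) {
  grid <- do.call(expand.grid, rep(list(seq_len(n)), k))
  keys <- apply(grid, 1L, function(r) paste(sort(r), collapse = ","))
  lapply(strsplit(unique(keys), ","), as.integer)
}

# Draw until exactly m distinct bootstrap multisets of size k from n.
drawDistinct <- function(n, k, m) {
  seen <- character(0)
  out <- vector("list", m)
  got <- 0L
  while (got < m) {
    s <- sort(sample.int(n, k, replace = TRUE))
    key <- paste(s, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    got <- got + 1L
    out[[got]] <- s
  }
  out
}
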