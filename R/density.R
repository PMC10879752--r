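# Density estimation and alpha/beta overlap between similarity distributions.

.DENSITY_FROM <- -0.05
.DENSITY_TO <- 1.05
.DENSITY_N <- 512L
.BW_FLOOR <- 1e-3

#' Kernel density estimate of a similarity distribution
#'
#' Gaussian-kernel density on a fixed 512-point grid over \[-0.05, 1.05\],
#' clipped to the mass on \[0, 1\] and renormalized (trapezoid rule).
#' Bandwidth is Silverman's rule-of-thumb with a floor of 1e-3. A sample
#' with (numerically) no spread is flagged `degenerate` and represented as a
#' spike of bandwidth equal to the floor so that overlap computations stay
#' defined; downstream code special-cases degenerate pairs.
#'
#' @param values numeric vector (at least 2 values), nominally in \[0,1\].
#' @return A [DensityEstimate-class].
#' @export
estimateDensity <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("at least 2 values are needed for a density estimate", call. = FALSE)
  degenerate <- stats::sd(values) < 1e-12
  bw <- if (degenerate) .BW_FLOOR else max(stats::bw.nrd0(values), .BW_FLOOR)
  d <- stats::density(values, bw = bw, from = .DENSITY_FROM, to = .DENSITY_TO,
                      n = .DENSITY_N)
  keep <- d$x >= 0 & d$x <= 1
  grid <- d$x[keep]
  dens <- d$y[keep]
  int <- .trapz(grid, dens)
  if (int <= 0) stop("density estimate carries no mass on [0, 1]", call. = FALSE)
  dens <- dens / int
  methods::new("DensityEstimate", grid = grid, density = dens, bandwidth = bw,
               degenerate = degenerate, center = mean(values))
}

# Interpolate a DensityEstimate onto an arbitrary grid (0 outside support).
.densOn <- function(den, grid) {
  stats::approx(den@grid, den@density, xout = grid, rule = 2L)$y
}

#' Alpha/beta overlap between a Test density and a reference density
#'
#' Quantifies how separable two similarity distributions are. With `T` the
#' Test density, `R` the reference density (Internal or Null), and `x` the
#' point between the two distribution means at which the Test first has
#' lower density than the reference:
#' \deqn{O_T = \int_x^1 T, \quad O_R = \int_0^x R, \quad
#'       \alpha = \frac{O_T}{2 - (O_T + O_R)}, \quad
#'       \beta = \frac{O_R}{2 - (O_T + O_R)}}
#' `alpha` plays the role of a false positive rate (Test mass reaching into
#' the reference's territory) and `beta` of a false negative rate. Disjoint
#' densities give `alpha = beta = 0`; identical densities give
#' `alpha = beta = 0.5`.
#'
#' The reference is expected to sit at or above the Test in the mean; if it
#' does not, the roles are exchanged and `swapped` is set so callers can
#' report the reversal. If no crossing exists between the means, `x` falls
#' back to their midpoint. Two degenerate (spike) densities yield 0/0 at
#' distinct locations and 0.5/0.5 at a common location.
#'
#' @param test,reference [DensityEstimate-class] objects.
#' @return An [OverlapResult-class].
#' @export
alphaBetaOverlap <- function(test, reference) {
  if (test@degenerate && reference@degenerate) {
    same <- abs(test@center - reference@center) <= 1e-9
    return(methods::new("OverlapResult",
                        alpha = if (same) 0.5 else 0,
                        beta = if (same) 0.5 else 0,
                        crossing = if (same) test@center
                                   else (test@center + reference@center) / 2,
                        swapped = FALSE))
  }
  swapped <- reference@center < test@center
  if (swapped) { tmp <- test; test <- reference; reference <- tmp }
  grid <- test@grid
  Td <- test@density
  Rd <- .densOn(reference, grid)
  lo <- test@center
  hi <- reference@center
  between <- which(grid >= lo & grid <= hi)
  x <- NA_real_
  if (length(between)) {
    below <- between[Td[between] < Rd[between]]
    if (length(below)) x <- grid[below[1L]]
  }
  if (is.na(x)) x <- (lo + hi) / 2
  upper <- grid >= x
  lower <- grid <= x
  oT <- if (sum(upper) >= 2L) .trapz(grid[upper], Td[upper]) else 0
  oR <- if (sum(lower) >= 2L) .trapz(grid[lower], Rd[lower]) else 0
  D <- 2 - (oT + oR)
  alpha <- min(max(oT / D, 0), 1)
  beta <- min(max(oR / D, 0), 1)
  methods::new("OverlapResult", alpha = alpha, beta = beta, crossing = x,
               swapped = swapped)
}

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf("OverlapResult: FPR (alpha) %.3f, FNR (beta) %.3f, crossing %.3f%s\n",
              object@alpha, object@beta, object@crossing,
              if (object@swapped) " [roles swapped]" else ""))
  invisible(NULL)
})
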