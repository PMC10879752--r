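# Plotting: general comparison, internal similarity, paired abundances.

.shadeRegion <- function(grid, dens, sel, col) {
  if (sum(sel) < 2L) return(invisible(NULL))
  graphics::polygon(c(grid[sel][1L], grid[sel], grid[sel][sum(sel)]),
                    c(0, dens[sel], 0), col = col, border = NA)
}

#' Plot the general Test-vs-Null comparison
#'
#' Test density in red, Null density in blue, the false positive region
#' (Test mass beyond the crossing point) shaded black and the false negative
#' region (Null mass short of it) shaded grey.
#'
#' @param dist a [SimilarityDistributions-class].
#' @param report optional [QualityReport-class] (recomputed if missing).
#' @param main plot title.
#' @export
plotGeneralComparison <- function(dist, report = NULL,
                                  main = "General comparison: Test vs Null") {
  dT <- estimateDensity(dist@test)
  dN <- estimateDensity(dist@null)
  ov <- if (is.null(report)) alphaBetaOverlap(dT, dN) else report@general
  ylim <- c(0, max(dT@density, dN@density))
  graphics::plot(dT@grid, dT@density, type = "l", col = "red", lwd = 2,
                 xlab = "similarity", ylab = "density", main = main,
                 ylim = ylim, xlim = c(0, 1))
  graphics::lines(dN@grid, dN@density, col = "blue", lwd = 2)
  lowerIsTest <- dT@center <= dN@center
  gT <- if (lowerIsTest) dT else dN
  gR <- if (lowerIsTest) dN else dT
  .shadeRegion(gT@grid, gT@density, gT@grid >= ov@crossing, "black")
  .shadeRegion(gR@grid, gR@density, gR@grid <= ov@crossing, "grey")
  graphics::abline(v = dist@observed@value, lty = 2)
  graphics::legend("topleft", bty = "n", lwd = c(2, 2, NA, NA), lty = c(1, 1, NA, NA),
                   col = c("red", "blue", "black", "grey"),
                   pch = c(NA, NA, 15, 15),
                   legend = c("Test", "Null",
                              sprintf("FPR %.1f%%", 100 * ov@alpha),
                              sprintf("FNR %.1f%%", 100 * ov@beta)))
  invisible(ov)
}

#' Plot a group's Internal similarity against the Test distribution
#'
#' Internal density in green, Test density in red, annotated with the
#' group's IC and the Internal-vs-Test FPR/FNR.
#'
#' @param dist a [SimilarityDistributions-class].
#' @param group `"A"` or `"B"`.
#' @param report optional [QualityReport-class].
#' @export
plotInternalSimilarity <- function(dist, group = c("A", "B"), report = NULL) {
  group <- match.arg(group)
  internal <- if (group == "A") dist@internalA else dist@internalB
  dI <- estimateDensity(internal)
  dT <- estimateDensity(dist@test)
  if (is.null(report)) {
    ov <- alphaBetaOverlap(dT, dI)
    ic <- as.numeric(internalConfidence(internal, dist@test, overlap = ov))
  } else {
    ov <- if (group == "A") report@overlapA else report@overlapB
    ic <- if (group == "A") report@icA else report@icB
  }
  ylim <- c(0, max(dI@density, dT@density))
  graphics::plot(dT@grid, dT@density, type = "l", col = "red", lwd = 2,
                 xlab = "similarity", ylab = "density",
                 main = sprintf("Internal similarity, group %s", group),
                 ylim = ylim, xlim = c(0, 1))
  graphics::lines(dI@grid, dI@density, col = "darkgreen", lwd = 2)
  graphics::legend("topleft", bty = "n", lwd = 2, col = c("darkgreen", "red"),
                   legend = c("Internal", "Test"))
  graphics::mtext(sprintf("IC = %.2f, FPR = %.1f%%, FNR = %.1f%%", ic,
                          100 * ov@alpha, 100 * ov@beta), side = 3, line = 0.2,
                  cex = 0.9)
  invisible(ic)
}

#' Paired per-glycopeptide abundance boxplots
#'
#' Side-by-side boxplots of the standardized log abundances of the two
#' groups, one pair per glycopeptide; zeros (missing) are omitted from the
#' boxes. Group A is drawn darker on the left of each pair, group B lighter
#' on the right.
#'
#' @param a,b standardized, aligned [GlycoProfile-class] objects.
#' @param main plot title.
#' @export
plotAbundancePairs <- function(a, b, main = "Relative log abundances") {
  ma <- abundanceMatrix(a); mb <- abundanceMatrix(b)
  .assertAligned(rownames(ma), rownames(mb), "profiles")
  n <- nrow(ma)
  vals <- list(); at <- numeric(0); cols <- character(0)
  for (g in seq_len(n)) {
    va <- ma[g, ]; vb <- mb[g, ]
    vals[[2L * g - 1L]] <- va[va > 0]
    vals[[2L * g]] <- vb[vb > 0]
    at <- c(at, 3 * g - 1, 3 * g)
    cols <- c(cols, "firebrick4", "lightsalmon")
  }
  graphics::boxplot(vals, at = at, col = cols, names = NA, xaxt = "n",
                    ylab = "standardized log abundance", main = main,
                    outline = TRUE, lty = 1)
  graphics::axis(1, at = 3 * seq_len(n) - 0.5, labels = rownames(ma),
                 las = 2, cex.axis = 0.55)
  graphics::legend("bottomleft", bty = "n", fill = c("firebrick4", "lightsalmon"),
                   legend = c(groupLabel(a), groupLabel(b)))
  invisible(NULL)
}
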