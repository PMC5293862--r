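# Invariance filtering across populations and PCA quality diagnostics.

#' Remove peaks invariant across populations
#'
#' Genotype-level medians (via [medianByGenotype()]) are compared across
#' populations with the Kruskal-Wallis test; peaks with `p > alpha` are
#' considered invariant and removed. Constant peaks are removed (no
#' evidence of variation is exactly what the filter targets).
#'
#' @param pe A [PeakExperiment] with at least two populations.
#' @param alpha Significance level (default 0.05).
#' @return Filtered `PeakExperiment`.
#' @export
filterInvariantPeaks <- function(pe, alpha = 0.05) {
  gm <- medianByGenotype(pe)
  pop <- factor(gm$population)
  if (nlevels(pop) < 2L)
    stop("invariance filtering needs >= 2 populations")
  empty <- setdiff(unique(colData(pe)$population[!colData(pe)$is_control]),
                   levels(pop))
  if (length(empty))
    stop("population with no genotypes: ", paste(empty, collapse = ", "))
  Y <- gm$matrix
  p <- apply(Y, 1L, function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 2L || nlevels(droplevels(pop[ok])) < 2L) return(1)
    if (stats::sd(v[ok]) == 0) return(1)  # constant: invariant by definition
    stats::kruskal.test(v[ok], droplevels(pop[ok]))$p.value
  })
  keep <- p <= alpha
  out <- pe[keep, ]
  .logStage(out, "invariance_filter", nrow(pe), sum(keep),
            list(criterion = sprintf(
      "Kruskal-Wallis across populations on genotype medians, p > %g removed",
      alpha)))
}

#' PCA quality diagnostics
#'
#' Principal components of the log-transformed, peak-centred matrix
#' (samples as observations). Used to check that bulk control samples
#' separate from experimental samples once batch effects are corrected.
#'
#' @param pe A [PeakExperiment] with at least 3 samples.
#' @param nComponents Number of components to return (default 2; at least
#'   2).
#' @param logOffset Offset for the log transform (default 1).
#' @return List with `scores` (samples x components), `varianceExplained`
#'   (fractions, non-increasing), and the sample metadata for plotting.
#' @export
pcaQc <- function(pe, nComponents = 2, logOffset = 1) {
  if (ncol(pe) < 3L)
    stop("PCA QC needs >= 3 samples")
  nComponents <- max(2L, as.integer(nComponents))
  Y <- .logT(intensities(pe), logOffset)
  Y[is.na(Y)] <- mean(Y, na.rm = TRUE)  # PCA needs complete data
  keep <- apply(Y, 1L, stats::sd) > 0
  pc <- stats::prcomp(t(Y[keep, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(nComponents, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       varianceExplained = ve[seq_len(k)],
       samples = sampleData(pe))
}
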