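# Population-level differential mining: genotype aggregation, moderated
# F-tests with FDR control, intensity-gated ranking.

#' Genotype-level median matrix
#'
#' Collapses clonal replicates to their median (missing values excluded;
#' a genotype with all replicates missing for a peak yields a missing
#' cell). Controls are excluded.
#'
#' @param pe A [PeakExperiment].
#' @return List with `matrix` (peaks x genotypes), `genotype` and
#'   `population` vectors aligned with the columns.
#' @export
medianByGenotype <- function(pe) {
  cd <- colData(pe)
  keep <- !cd$is_control
  x <- intensities(pe)[, keep, drop = FALSE]
  geno <- factor(cd$genotype[keep])
  lev <- levels(geno)
  out <- matrix(NA_real_, nrow(x), length(lev),
                dimnames = list(rownames(x), lev))
  for (g in seq_along(lev))
    out[, g] <- apply(x[, geno == lev[g], drop = FALSE], 1L,
                      function(v) if (all(is.na(v))) NA_real_
                      else stats::median(v, na.rm = TRUE))
  pop <- cd$population[keep][match(lev, as.character(geno))]
  list(matrix = out, genotype = lev, population = as.character(pop))
}

#' Moderated one-way population test
#'
#' For each peak a one-way model of log intensity across populations is
#' fitted on genotype-level medians. Residual variances are shrunk toward
#' a common prior by empirical Bayes: the prior degrees of freedom `d0`
#' and scale `s0^2` are estimated by moment equations on the log residual
#' variances (via [limma::fitFDist]), the posterior variance is
#' `(d0*s0^2 + df*s^2) / (d0 + df)`, and the moderated F is the
#' between-population mean square over the posterior variance, with p from
#' an F distribution on `(k-1, d0 + df)` degrees of freedom.
#' Benjamini-Hochberg adjustment controls the FDR.
#'
#' With `priorDf = 0` the test reduces exactly to the classical one-way
#' ANOVA F; with `priorDf = Inf` every peak is tested against the common
#' prior variance.
#'
#' @param pe A [PeakExperiment] with >= 2 populations and more genotypes
#'   than populations.
#' @param priorDf Optional override of the estimated prior degrees of
#'   freedom (`0`, `Inf`, or a positive number).
#' @param priorVar Optional override of the prior variance `s0^2`.
#' @param logOffset Offset for the log transform (default 1).
#' @param fdrMethod Multiple-testing method passed to [stats::p.adjust]
#'   (default `"BH"`).
#' @return `data.frame` (one row per testable peak): `peak_id`,
#'   `F` (moderated), `p`, `p_adjust`, `mean_intensity` (raw scale),
#'   `df1`, `df2`, plus the fitted `priorDf`/`priorVar` as attributes.
#'   All-missing peaks are excluded with a warning.
#' @export
moderatedPopulationTest <- function(pe, priorDf = NULL, priorVar = NULL,
                                    logOffset = 1, fdrMethod = "BH") {
  gm <- medianByGenotype(pe)
  pop <- factor(gm$population)
  if (nlevels(pop) < 2L)
    stop("population test needs >= 2 populations")
  if (ncol(gm$matrix) <= nlevels(pop))
    stop("need more genotypes than populations for residual variance")
  allMissing <- rowSums(!is.na(gm$matrix)) == 0L
  if (any(allMissing))
    warning(sum(allMissing), " all-missing peaks excluded")
  Y <- .logT(gm$matrix[!allMissing, , drop = FALSE], logOffset)
  raw <- gm$matrix[!allMissing, , drop = FALSE]
  an <- .rowOnewayF(Y, pop)

  s2 <- an$msw
  df <- an$df2
  usable <- is.finite(s2) & s2 > 0 & df > 0
  if (is.null(priorDf) || is.null(priorVar)) {
    if (sum(usable) < 2L) {
      # too few informative peaks to fit a prior: unmoderated fallback
      warning("fewer than 2 peaks with residual variance; ",
              "falling back to the classical F-test")
      if (is.null(priorDf)) priorDf <- 0
      if (is.null(priorVar)) priorVar <- 1
    } else {
      fit <- limma::fitFDist(s2[usable], df1 = df[usable])
      if (is.null(priorDf)) priorDf <- fit$df2
      if (is.null(priorVar)) priorVar <- fit$scale
    }
  }
  stopifnot(priorDf >= 0, priorVar > 0 || priorDf == 0)

  if (is.infinite(priorDf)) {
    varPost <- rep(priorVar, length(s2))
    dfTot <- rep(Inf, length(s2))
  } else if (priorDf == 0) {
    varPost <- s2
    dfTot <- df
  } else {
    varPost <- (priorDf * priorVar + df * s2) / (priorDf + df)
    varPost[!usable] <- priorVar  # no residual info: prior only
    dfTot <- priorDf + df
  }
  Fmod <- an$msb / varPost
  Fmod[an$df1 == 0] <- NA_real_
  p <- stats::pf(Fmod, an$df1, dfTot, lower.tail = FALSE)
  zeroB <- !is.na(an$msb) & an$msb <= 1e-12
  Fmod[zeroB] <- 0
  p[zeroB] <- 1
  res <- data.frame(
    peak_id = rownames(Y),
    F = Fmod, p = p,
    p_adjust = stats::p.adjust(p, method = fdrMethod),
    mean_intensity = rowMeans(raw, na.rm = TRUE),
    df1 = an$df1, df2 = dfTot,
    stringsAsFactors = FALSE
  )
  attr(res, "priorDf") <- priorDf
  attr(res, "priorVar") <- priorVar
  res
}

#' Intensity-gated top-k ranking of differential peaks
#'
#' Restricts a differential result to intense peaks (mean raw intensity
#' above `intensityMin`), ranks by moderated F descending with ties broken
#' by peak id, and returns the first `k`.
#'
#' @param result Output of [moderatedPopulationTest()].
#' @param intensityMin Mean-intensity gate (default 1e5).
#' @param k Number of peaks to return (default 50).
#' @return The gated, ranked `data.frame` with a `rank` column; if fewer
#'   than `k` peaks pass the gate, all are returned with a message.
#' @export
rankTopPeaks <- function(result, intensityMin = 1e5, k = 50) {
  gated <- result[!is.na(result$mean_intensity) &
                    result$mean_intensity > intensityMin &
                    !is.na(result$F), , drop = FALSE]
  gated <- gated[order(-gated$F, gated$peak_id), , drop = FALSE]
  if (nrow(gated) < k)
    message("only ", nrow(gated), " peaks pass the intensity gate (k = ",
            k, "): returning all")
  out <- utils::head(gated, k)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
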