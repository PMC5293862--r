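# Parametric empirical-Bayes batch correction (location/scale model) and
# residual-batch F filtering.
#
# Model, on natural-log intensities: y_pbs = alpha_p + gamma_pb +
# delta_pb * eps_pbs. Per-peak data are standardised, additive batch
# effects (gamma) are shrunk toward a normal prior and multiplicative ones
# (delta^2) toward an inverse-gamma prior, with prior hyperparameters fitted
# by the method of moments across peaks; posterior estimates are found by
# the standard iterative EB solution and removed, and the data are returned
# on the original intensity scale.

#' Correct batch effects by parametric empirical Bayes
#'
#' @param pe A [PeakExperiment] with at least two batches, each containing
#'   at least two samples.
#' @param logOffset Offset added before the natural-log transform
#'   (default 1).
#' @param conv Relative convergence tolerance of the iterative EB solution
#'   for the posterior batch effects (default 1e-4).
#' @return A `PeakExperiment` of identical dimensions with batch location
#'   and scale effects removed.
#' @export
correctBatchEffects <- function(pe, logOffset = 1, conv = 1e-4) {
  batch <- factor(colData(pe)$batch)
  tab <- table(batch)
  if (length(tab) < 2L)
    stop("batch correction needs >= 2 batches")
  small <- names(tab)[tab < 2L]
  if (length(small))
    stop("batch with < 2 samples: ", paste(small, collapse = ", "))
  x <- intensities(pe)
  Y <- .logT(x, logOffset)
  adj <- .ebBatchAdjust(Y, batch, conv = conv)
  out <- pe
  corrected <- .logTInv(adj, logOffset)
  corrected[is.na(x)] <- NA_real_
  SummarizedExperiment::assay(out, "intensity") <- corrected
  .logStage(out, "batch_correction", nrow(pe), nrow(pe),
            list(criterion = "parametric empirical Bayes location/scale",
                 batches = length(tab)))
}

# Core EB adjustment on a log-scale matrix (peaks x samples). Vectorised
# over peaks; NA-aware. Returns the adjusted matrix on the log scale.
.ebBatchAdjust <- function(Y, batch, conv = 1e-4) {
  batch <- factor(batch)
  lev <- levels(batch)
  nb <- length(lev)
  npk <- nrow(Y)

  nMat <- matrix(0L, npk, nb)        # non-missing count per peak x batch
  meanMat <- matrix(NA_real_, npk, nb)
  for (b in seq_len(nb)) {
    sub <- Y[, batch == lev[b], drop = FALSE]
    ok <- !is.na(sub)
    nMat[, b] <- rowSums(ok)
    sub0 <- sub; sub0[!ok] <- 0
    meanMat[, b] <- rowSums(sub0) / nMat[, b]
  }
  nTot <- rowSums(nMat)
  # grand mean weighted by batch sample counts (columns of the batch design)
  grand <- rowSums(meanMat * nMat, na.rm = TRUE) / nTot
  # pooled residual variance about batch means, denominator n (not n-1)
  resid <- Y - meanMat[, as.integer(batch), drop = FALSE]
  varPooled <- rowSums(resid^2, na.rm = TRUE) / nTot
  varPooled[varPooled <= 0] <- NA_real_  # flat peaks: leave untouched
  sdPooled <- sqrt(varPooled)

  Z <- (Y - grand) / sdPooled

  gammaHat <- matrix(NA_real_, npk, nb)
  deltaHat <- matrix(NA_real_, npk, nb)
  for (b in seq_len(nb)) {
    sub <- Z[, batch == lev[b], drop = FALSE]
    gammaHat[, b] <- rowMeans(sub, na.rm = TRUE)
    deltaHat[, b] <- apply(sub, 1L, stats::var, na.rm = TRUE)
  }

  gammaStar <- gammaHat
  deltaStar <- deltaHat
  for (b in seq_len(nb)) {
    ok <- is.finite(gammaHat[, b]) & is.finite(deltaHat[, b]) &
      deltaHat[, b] > 0
    if (sum(ok) < 2L) { # too few peaks to fit priors: leave estimates as is
      deltaStar[!is.finite(deltaStar[, b]) | deltaStar[, b] <= 0, b] <- 1
      next
    }
    g <- gammaHat[ok, b]; d <- deltaHat[ok, b]; n <- nMat[ok, b]
    gBar <- mean(g); t2 <- stats::var(g)
    m <- mean(d); s2 <- stats::var(d)
    aPrior <- (2 * s2 + m^2) / s2
    bPrior <- (m * s2 + m^3) / s2
    sub <- Z[ok, batch == lev[b], drop = FALSE]
    sol <- .ebIterSolve(sub, g, d, n, gBar, t2, aPrior, bPrior, conv)
    gammaStar[ok, b] <- sol$gamma
    deltaStar[ok, b] <- sol$delta
    # peaks where moments were undefined: remove raw batch mean, unit scale
    deltaStar[!ok, b] <- 1
    gammaStar[!ok, b] <- ifelse(is.finite(gammaHat[!ok, b]),
                                gammaHat[!ok, b], 0)
  }

  bi <- as.integer(batch)
  Zadj <- (Z - gammaStar[, bi, drop = FALSE]) /
    sqrt(deltaStar)[, bi, drop = FALSE]
  out <- Zadj * sdPooled + grand
  flat <- !is.finite(varPooled)
  out[flat, ] <- Y[flat, ]
  out
}

# Iterative EB solution for one batch: alternate posterior location
# (normal prior) and posterior scale (inverse-gamma prior) until the
# largest relative change falls below conv.
.ebIterSolve <- function(Zb, gHat, dHat, n, gBar, t2, aPrior, bPrior, conv) {
  gOld <- gHat
  dOld <- dHat
  repeat {
    gNew <- (t2 * n * gHat + dOld * gBar) / (t2 * n + dOld)
    sum2 <- rowSums((Zb - gNew)^2, na.rm = TRUE)
    dNew <- (0.5 * sum2 + bPrior) / (n / 2 + aPrior - 1)
    change <- max(abs(gNew - gOld) / abs(gOld),
                  abs(dNew - dOld) / abs(dOld), na.rm = TRUE)
    gOld <- gNew
    dOld <- dNew
    if (!is.finite(change) || change < conv) break
  }
  list(gamma = gOld, delta = dOld)
}

#' Remove peaks with residual batch effects
#'
#' One-way ANOVA of log intensity on batch, per peak; peaks with
#' `p < alpha` are removed. Peaks that are constant across batches have no
#' testable batch effect and are retained (`p` defined as 1).
#'
#' @param pe A [PeakExperiment] (normally after [correctBatchEffects()]).
#' @param alpha Significance level (default 0.05).
#' @param logOffset Offset for the log transform (default 1).
#' @return Filtered `PeakExperiment`.
#' @export
filterResidualBatch <- function(pe, alpha = 0.05, logOffset = 1) {
  Y <- .logT(intensities(pe), logOffset)
  res <- .rowOnewayF(Y, colData(pe)$batch)
  keep <- is.na(res$p) | res$p >= alpha
  out <- pe[keep, ]
  .logStage(out, "residual_batch_filter", nrow(pe), sum(keep),
            list(criterion = sprintf("batch ANOVA p < %g removed", alpha)))
}
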