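# Replicate-level quality statistics: coefficient of variation across
# clonal replicates, modified Z-scores, and outlier removal within the
# most varied replicate groups.

#' Replicate coefficient of variation report
#'
#' For every (peak, genotype) cell the cv = sd/mean across that genotype's
#' clonal replicates is computed (controls excluded, missing values
#' excluded pairwise; genotypes with fewer than two non-missing replicates
#' for a peak yield an undefined cv that is excluded from the median).
#' Each peak is then summarised by its median cv across genotypes.
#'
#' @param pe A [PeakExperiment].
#' @param cvThreshold Threshold used for the summary fraction
#'   (default 0.3).
#' @return List with `perGenotype` (peaks x genotypes cv matrix),
#'   `medianCv` (per peak), and `fractionBelow` (fraction of peaks with
#'   median cv below `cvThreshold`).
#' @export
replicateCv <- function(pe, cvThreshold = 0.3) {
  cd <- colData(pe)
  keep <- !cd$is_control
  x <- intensities(pe)[, keep, drop = FALSE]
  geno <- factor(cd$genotype[keep])
  lev <- levels(geno)
  cv <- matrix(NA_real_, nrow(x), length(lev),
               dimnames = list(rownames(x), lev))
  for (g in seq_along(lev)) {
    sub <- x[, geno == lev[g], drop = FALSE]
    nOk <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    v <- sdv / mu
    v[nOk < 2L | !is.finite(v)] <- NA_real_
    cv[, g] <- v
  }
  med <- apply(cv, 1L, function(v)
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
  frac <- mean(med < cvThreshold, na.rm = TRUE)
  list(perGenotype = cv, medianCv = med, fractionBelow = frac,
       cvThreshold = cvThreshold)
}

#' Modified Z-scores
#'
#' `Z_i = 0.6745 * (x_i - median(x)) / mad(x)` with mad the unscaled median
#' absolute deviation. When mad is 0 (at least half the values identical)
#' every score is defined as 0, so constant replicate groups flag no
#' outliers.
#'
#' @param values Numeric vector of length >= 2 (`NA` allowed; scores for
#'   `NA` entries are `NA`).
#' @return Numeric vector of modified Z-scores, same length as `values`.
#' @examples
#' modifiedZscore(c(1, 2, 3, 4, 100))
#' @export
modifiedZscore <- function(values) {
  if (length(values) < 2L)
    stop("modified Z-scores need at least 2 values")
  med <- stats::median(values, na.rm = TRUE)
  if (is.na(med)) return(rep(NA_real_, length(values)))
  madU <- stats::median(abs(values - med), na.rm = TRUE)
  if (madU == 0) {
    z <- rep(0, length(values))
    z[is.na(values)] <- NA_real_
    return(z)
  }
  0.6745 * (values - med) / madU
}

#' Remove outlying replicates within varied replicate groups
#'
#' Replicate groups (one genotype's clonal replicates for one peak) with
#' cv above `cvTrigger` are examined; within them, replicates whose
#' absolute modified Z-score exceeds `zThreshold` are set to missing. At
#' most `floor(n/2)` replicates are removed per group (those with the
#' largest |Z| first), so a group can never lose its majority.
#'
#' @param pe A [PeakExperiment].
#' @param cvTrigger cv level above which a group is examined
#'   (default 0.2).
#' @param zThreshold Absolute modified Z-score for removal (default 3.0).
#' @return A `PeakExperiment` with flagged cells set to `NA`.
#' @export
removeReplicateOutliers <- function(pe, cvTrigger = 0.2, zThreshold = 3.0) {
  cd <- colData(pe)
  x <- intensities(pe)
  geno <- factor(cd$genotype)
  removed <- 0L
  for (lev in levels(geno)) {
    cols <- which(geno == lev & !cd$is_control)
    if (length(cols) < 2L) next
    sub <- x[, cols, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    cv <- sdv / mu
    rows <- which(is.finite(cv) & cv > cvTrigger)
    for (r in rows) {
      v <- sub[r, ]
      z <- modifiedZscore(v)
      flag <- which(!is.na(z) & abs(z) > zThreshold)
      if (!length(flag)) next
      cap <- floor(sum(!is.na(v)) / 2)
      if (length(flag) > cap)
        flag <- flag[order(-abs(z[flag]))][seq_len(cap)]
      x[r, cols[flag]] <- NA_real_
      removed <- removed + length(flag)
    }
  }
  out <- pe
  SummarizedExperiment::assay(out, "intensity") <- x
  .logStage(out, "replicate_outlier_removal", nrow(pe), nrow(pe),
            list(criterion = sprintf("group cv > %g & |Z| > %g",
                                     cvTrigger, zThreshold),
                 cells_removed = removed))
}
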