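# Shared statistical helpers.

# Natural-log transform with offset used by every model-based stage.
.logT <- function(x, offset = 1) log(x + offset)
.logTInv <- function(y, offset = 1) pmax(exp(y) - offset, 0)

# Row-wise one-way ANOVA of a peaks x samples matrix on a grouping factor.
# Missing values are excluded pairwise. Returns per-row F, p, df and the
# between / within mean squares. Rows with no within-group variation get
# p = 1 when also flat between groups, p = 0 when between-group variation
# remains (F formally infinite).
.rowOnewayF <- function(Y, groups) {
  groups <- factor(groups)
  lev <- levels(groups)
  k <- length(lev)
  npk <- nrow(Y)
  sumG <- matrix(0, npk, k)
  nG <- matrix(0L, npk, k)
  ssG <- matrix(0, npk, k)
  for (g in seq_len(k)) {
    cols <- which(groups == lev[g])
    sub <- Y[, cols, drop = FALSE]
    ok <- !is.na(sub)
    nG[, g] <- rowSums(ok)
    sub0 <- sub; sub0[!ok] <- 0
    sumG[, g] <- rowSums(sub0)
    ssG[, g] <- rowSums(sub0^2)
  }
  nTot <- rowSums(nG)
  grand <- rowSums(sumG) / nTot
  meanG <- sumG / nG  # NaN where a group is empty for that row
  kEff <- rowSums(nG > 0)
  ssb <- rowSums(nG * (meanG - grand)^2, na.rm = TRUE)
  ssw <- rowSums(ssG - nG * meanG^2, na.rm = TRUE)
  ssw <- pmax(ssw, 0)  # guard tiny negative rounding
  df1 <- kEff - 1L
  df2 <- nTot - kEff
  msb <- ifelse(df1 > 0, ssb / df1, NA_real_)
  msw <- ifelse(df2 > 0, ssw / df2, NA_real_)
  Fstat <- msb / msw
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  # degenerate rows: no residual variation
  flatW <- !is.na(msw) & msw <= 1e-12 * pmax(1, grand^2)
  flatB <- ssb <= 1e-12 * pmax(1, grand^2)
  p[flatW & flatB] <- 1
  Fstat[flatW & flatB] <- 0
  p[flatW & !flatB] <- 0
  Fstat[flatW & !flatB] <- Inf
  p[df1 == 0 | df2 == 0] <- 1
  data.frame(F = Fstat, p = p, df1 = df1, df2 = df2, msb = msb, msw = msw,
             mean = grand, n = nTot)
}

# Row medians with NA removal (no matrixStats dependency; tables are small).
.rowMedians <- function(Y) apply(Y, 1L, stats::median, na.rm = TRUE)
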