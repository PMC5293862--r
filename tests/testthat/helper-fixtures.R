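# Fixture builders and independent oracles used across the suite.

# Minimal PeakExperiment around an intensity matrix.
makeToyPe <- function(x, mz, rt, meta = NULL, ionMode = "positive",
                      rtHalfWidth = 0.05) {
  n <- ncol(x)
  if (is.null(meta)) {
    meta <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      population = "P01",
      genotype = sprintf("g%03d", ceiling(seq_len(n) / 5)),
      replicate = ((seq_len(n) - 1L) %% 5L) + 1L,
      batch = "B01", ion_mode = ionMode, is_control = FALSE,
      stringsAsFactors = FALSE)
  }
  annot <- data.frame(
    peak_id = sprintf("pk%03d", seq_along(mz)),
    mz = mz, rt = rt, rtmin = rt - rtHalfWidth, rtmax = rt + rtHalfWidth,
    mzmin = mz - 1e-3, mzmax = mz + 1e-3,
    ion_mode = rep(ionMode, length(mz)),
    adduct = rep("unknown", length(mz)),
    isotope_links = rep("", length(mz)),
    stringsAsFactors = FALSE)
  PeakExperiment(x, annot, meta)
}

# Random table with planted isotope envelopes and decoys that fail each
# criterion in turn; intensities over `nSamples` samples.
randomIsotopeTable <- function(seed, nPeaks = 50, nSamples = 20) {
  set.seed(seed)
  mzs <- numeric(0); rts <- numeric(0); rows <- list()
  addPeak <- function(mz, rt, vals) {
    mzs <<- c(mzs, mz); rts <<- c(rts, rt)
    rows[[length(rows) + 1L]] <<- vals
  }
  nPlant <- sample(4:8, 1L)
  for (i in seq_len(nPlant)) {
    mz <- runif(1, 150, 900)
    rt <- runif(1, 1, 9)
    base <- exp(rnorm(nSamples, log(1e6), 1))
    kind <- sample(c("good3", "good2", "badRatio", "badCor", "badRt"), 1L)
    addPeak(mz, rt, base)
    r1 <- runif(1, 0.15, 0.45)  # passing [M+1]/[M]
    if (kind == "badRatio") r1 <- runif(1, 0.6, 0.9)
    v1 <- base * r1 * exp(rnorm(nSamples, 0, 0.02))
    if (kind == "badCor") v1 <- exp(rnorm(nSamples, log(mean(base) * r1), 1))
    rtOff <- if (kind == "badRt") 0.35 else runif(1, -0.05, 0.05)
    addPeak(mz + 1.00336 * (1 + runif(1, -3e-6, 3e-6)), rt + rtOff, v1)
    if (kind == "good3") {
      v2 <- v1 * runif(1, 0.15, 0.45) * exp(rnorm(nSamples, 0, 0.02))
      addPeak(mz + 2 * 1.00336, rt + runif(1, -0.05, 0.05), v2)
    }
  }
  while (length(rows) < nPeaks) {
    addPeak(runif(1, 100, 1000), runif(1, 0.5, 10),
            exp(rnorm(nSamples, log(1e5), 1.5)))
  }
  x <- do.call(rbind, rows)[seq_len(nPeaks), , drop = FALSE]
  makeToyPe(x, mzs[seq_len(nPeaks)], rts[seq_len(nPeaks)])
}

# Exhaustive de-isotoping oracle: tests every candidate pair/triple
# against the four criteria (ppm-window spacing, RT window, correlation,
# mean-intensity ratios), then applies the documented greedy disjointness
# rule (descending [M] mean intensity, partner closest to the expected
# spacing, ties by ascending m/z).
oracleIsotopeGroups <- function(pe, ppmTol = 20, rtTol = 0.2, rMin = 0.9,
                                ratioMin = 2) {
  x <- intensities(pe)
  rd <- peakData(pe)
  mz <- rd$mz; rt <- rd$rt; ids <- rd$peak_id
  n <- length(ids)
  meanInt <- rowMeans(x, na.rm = TRUE)
  spacingOk <- function(i, j) {
    target <- mz[i] + 1.00336
    abs(mz[j] - target) <= target * ppmTol / 1e6 &&
      abs(rt[i] - rt[j]) <= rtTol
  }
  corOk <- function(i, j) {
    ok <- !is.na(x[i, ]) & !is.na(x[j, ])
    if (sum(ok) < 3L) return(FALSE)
    if (sd(x[i, ok]) == 0 || sd(x[j, ok]) == 0) return(FALSE)
    cor(x[i, ok], x[j, ok]) > rMin
  }
  used <- rep(FALSE, n)
  out <- list()
  for (i in order(-meanInt, mz)) {
    if (used[i]) next
    cand <- setdiff(which(!used), i)
    cand <- cand[vapply(cand, function(j) spacingOk(i, j), TRUE)]
    if (!length(cand)) next
    tgt <- mz[i] + 1.00336
    j <- cand[order(abs(mz[cand] - tgt), mz[cand])][1L]
    if (!corOk(i, j)) next
    if (!(meanInt[i] / meanInt[j] > ratioMin)) next
    cand2 <- setdiff(which(!used), c(i, j))
    cand2 <- cand2[vapply(cand2, function(k) spacingOk(j, k), TRUE)]
    k <- NA_integer_
    if (length(cand2)) {
      tgt2 <- mz[j] + 1.00336
      k0 <- cand2[order(abs(mz[cand2] - tgt2), mz[cand2])][1L]
      if (corOk(i, k0) && meanInt[j] / meanInt[k0] > ratioMin) k <- k0
    }
    used[c(i, j)] <- TRUE
    if (!is.na(k)) used[k] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      monoisotopic = ids[i], plus_one = ids[j],
      plus_two = if (is.na(k)) NA_character_ else ids[k],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(monoisotopic = character(0), plus_one = character(0),
                      plus_two = character(0)))
  do.call(rbind, out)
}

# Brute-force UPGMA: explicit agglomeration returning the cophenetic
# distance matrix (merge-distance scale), which fully determines the
# UPGMA tree (topology + heights).
oracleUpgmaCophenetic <- function(D) {
  D <- as.matrix(D)
  labs <- rownames(D)
  clusters <- as.list(seq_along(labs))
  sizes <- rep(1, length(labs))
  coph <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  d <- D
  active <- seq_along(labs)
  while (length(active) > 1L) {
    best <- c(NA, NA); bestD <- Inf
    for (ai in seq_along(active)) for (bi in seq_along(active)) {
      if (bi <= ai) next
      a <- active[ai]; b <- active[bi]
      if (d[a, b] < bestD) { bestD <- d[a, b]; best <- c(a, b) }
    }
    a <- best[1L]; b <- best[2L]
    for (la in clusters[[a]]) for (lb in clusters[[b]]) {
      coph[la, lb] <- bestD; coph[lb, la] <- bestD
    }
    for (cC in setdiff(active, c(a, b)))
      d[a, cC] <- d[cC, a] <-
        (sizes[a] * d[a, cC] + sizes[b] * d[b, cC]) / (sizes[a] + sizes[b])
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  coph
}

# Direct, non-vectorised coding of the parametric EB location/scale batch
# adjustment (per-batch loops, explicit moment estimates and iteration).
oracleEbBatchAdjust <- function(Y, batch, conv = 1e-4) {
  batch <- factor(batch)
  lev <- levels(batch)
  npk <- nrow(Y); n <- ncol(Y)
  out <- Y
  grand <- numeric(npk); varPooled <- numeric(npk)
  for (p in seq_len(npk)) {
    bm <- tapply(Y[p, ], batch, mean)
    nb <- tapply(Y[p, ], batch, length)
    grand[p] <- sum(bm * nb) / n
    varPooled[p] <- sum((Y[p, ] - bm[as.character(batch)])^2) / n
  }
  Z <- (Y - grand) / sqrt(varPooled)
  for (b in lev) {
    cols <- which(batch == b)
    nb <- length(cols)
    gHat <- numeric(npk); dHat <- numeric(npk)
    for (p in seq_len(npk)) {
      gHat[p] <- mean(Z[p, cols])
      dHat[p] <- var(Z[p, cols])
    }
    gBar <- mean(gHat); t2 <- var(gHat)
    m <- mean(dHat); s2 <- var(dHat)
    aP <- (2 * s2 + m^2) / s2
    bP <- (m * s2 + m^3) / s2
    gOld <- gHat; dOld <- dHat
    repeat {
      gNew <- numeric(npk); dNew <- numeric(npk)
      for (p in seq_len(npk)) {
        gNew[p] <- (t2 * nb * gHat[p] + dOld[p] * gBar) /
          (t2 * nb + dOld[p])
        sum2 <- sum((Z[p, cols] - gNew[p])^2)
        dNew[p] <- (0.5 * sum2 + bP) / (nb / 2 + aP - 1)
      }
      change <- max(abs(gNew - gOld) / abs(gOld),
                    abs(dNew - dOld) / abs(dOld))
      gOld <- gNew; dOld <- dNew
      if (change < conv) break
    }
    for (p in seq_len(npk))
      out[p, cols] <- (Z[p, cols] - gOld[p]) / sqrt(dOld[p]) *
        sqrt(varPooled[p]) + grand[p]
  }
  out
}

# Brute-force moiety multiset search (all multisets up to maxN).
oracleMoietySets <- function(residual, moieties, tolDa, maxN = 3) {
  found <- list()
  syms <- moieties$symbol
  recur <- function(start, chosen) {
    s <- sum(moieties$lossMass[chosen])
    if (length(chosen) && abs(s - residual) <= tolDa)
      found[[length(found) + 1L]] <<- sort(syms[chosen])
    if (length(chosen) >= maxN) return()
    for (i in start:length(syms)) recur(i, c(chosen, i))
  }
  recur(1L, integer(0))
  unique(found)
}

# Shared fast-preset fixture: generated once per test run.
fastFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- designSpec(seed = 42)
      design <- generateDesign(spec)
      truth <- simulateTruth(spec)
      cache <<- renderIntensityMatrix(truth, design, seed = 43)
    }
    cache
  }
})

# drop row names before structural comparison
stripRn <- function(d) { rownames(d) <- NULL; d }

# do the members of an accepted group satisfy the four criteria at the
# given thresholds? (spacing, RT, correlation with [M], mean ratios)
groupMeetsCriteria <- function(pe, mono, p1, p2, ppmTol, rtTol, rMin,
                               ratioMin) {
  x <- intensities(pe); rd <- peakData(pe)
  idx <- match(c(mono, p1, p2), rd$peak_id)
  meanInt <- rowMeans(x[idx[!is.na(idx)], , drop = FALSE], na.rm = TRUE)
  pairOk <- function(a, b) {
    target <- rd$mz[a] + 1.00336
    abs(rd$mz[b] - target) <= target * ppmTol / 1e6 &&
      abs(rd$rt[a] - rd$rt[b]) <= rtTol &&
      cor(x[a, ], x[b, ], use = "pairwise.complete.obs") > rMin
  }
  ok <- pairOk(idx[1], idx[2]) &&
    mean(x[idx[1], ], na.rm = TRUE) / mean(x[idx[2], ], na.rm = TRUE) >
      ratioMin
  if (!is.na(p2) && ok) {
    ok <- pairOk(idx[2], idx[3]) &&
      cor(x[idx[1], ], x[idx[3], ], use = "pairwise.complete.obs") > rMin &&
      mean(x[idx[2], ], na.rm = TRUE) / mean(x[idx[3], ], na.rm = TRUE) >
        ratioMin
  }
  isTRUE(ok)
}
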