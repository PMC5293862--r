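# Synthetic multi-batch LC-MS experiment generator.
#
# Emulates a clonally replicated population survey assayed in randomized
# batches: population-specific metabolite presence/absence, clonal
# (genotype) biological variation, log-normal replicate noise with a
# target cv, per-batch location/scale effects on log intensity, per-batch
# retention-time drift that splits closely eluting isomers into extra peak
# rows, isotope envelopes following the binomial 13C model, in-source
# fragment rows for glycosides, duplicate detections, and injected
# replicate outliers. Every random choice is governed by the design seed,
# and the full ground truth is returned as a TruthSet.

#' Design specification for a synthetic experiment
#'
#' The `"fast"` preset (10 populations x 6 genotypes x 5 clonal replicates
#' x 12 batches, 2 bulk controls per batch) keeps simulations small while
#' preserving the structure of a large survey; the `"full"` preset matches
#' a 23-population, 233-genotype, 36-batch design.
#'
#' @param nPopulations Number of populations.
#' @param genotypesPerPopulation Inclusive integer range
#'   `c(min, max)` of genotypes per population.
#' @param nReplicates Clonal replicates per genotype.
#' @param nBatches Number of analytical batches.
#' @param controlsPerBatch Bulk control samples per batch.
#' @param ionMode `"positive"` or `"negative"`.
#' @param seed Integer seed; fully determines all downstream randomness.
#' @param targetGenotypes Optional total genotype count the drawn
#'   per-population counts are adjusted to (used by the `"full"` preset).
#' @param preset `"fast"`, `"full"`, or `"custom"` (use the explicit
#'   arguments).
#' @return List of class `designSpec`.
#' @export
designSpec <- function(preset = c("fast", "full", "custom"),
                       nPopulations = 10,
                       genotypesPerPopulation = c(6, 6),
                       nReplicates = 5,
                       nBatches = 12,
                       controlsPerBatch = 2,
                       ionMode = "positive",
                       seed = 1L,
                       targetGenotypes = NULL) {
  preset <- match.arg(preset)
  if (preset == "full") {
    nPopulations <- 23
    genotypesPerPopulation <- c(3, 25)
    nReplicates <- 5
    nBatches <- 36
    controlsPerBatch <- 2
    targetGenotypes <- 233
  }
  spec <- list(nPopulations = nPopulations,
               genotypesPerPopulation = genotypesPerPopulation,
               nReplicates = nReplicates,
               nBatches = nBatches,
               controlsPerBatch = controlsPerBatch,
               ionMode = ionMode,
               seed = as.integer(seed),
               targetGenotypes = targetGenotypes)
  .validateDesignSpec(spec)
  class(spec) <- "designSpec"
  spec
}

.validateDesignSpec <- function(spec) {
  chk <- function(ok, field, why)
    if (!ok) stop("invalid design spec: field '", field, "' ", why,
                  call. = FALSE)
  chk(is.numeric(spec$nPopulations) && spec$nPopulations >= 1,
      "nPopulations", "must be >= 1")
  g <- spec$genotypesPerPopulation
  chk(length(g) == 2L && g[1] >= 1 && g[1] <= g[2],
      "genotypesPerPopulation", "must be an increasing range with min >= 1")
  chk(spec$nReplicates >= 1, "nReplicates", "must be >= 1")
  chk(spec$nBatches >= 1, "nBatches", "must be >= 1")
  chk(spec$controlsPerBatch >= 0, "controlsPerBatch", "must be >= 0")
  chk(spec$ionMode %in% c("positive", "negative"), "ionMode",
      "must be 'positive' or 'negative'")
  chk(is.finite(spec$seed), "seed", "must be a finite integer")
  invisible(TRUE)
}

#' Generate the sample design of a synthetic experiment
#'
#' Draws per-population genotype counts, assigns genotype x replicate
#' samples to batches by randomized near-equal blocks, and adds the
#' per-batch bulk control samples. The assignment guarantees that (when
#' the design allows it) at least one genotype's replicates span two or
#' more batches, and that every batch contains at least one control when
#' controls are requested.
#'
#' @param spec A [designSpec()].
#' @return `data.frame` with columns `sample_id`, `population`, `genotype`,
#'   `replicate`, `batch`, `ion_mode`, `is_control`.
#' @export
generateDesign <- function(spec) {
  .validateDesignSpec(spec)
  set.seed(spec$seed)
  npop <- spec$nPopulations
  g <- spec$genotypesPerPopulation
  counts <- if (g[1] == g[2]) rep(g[1], npop)
            else sample(seq(g[1], g[2]), npop, replace = TRUE)
  if (!is.null(spec$targetGenotypes)) {
    # nudge drawn counts (within the range) until the total matches
    i <- 1L
    while (sum(counts) != spec$targetGenotypes) {
      if (sum(counts) < spec$targetGenotypes && counts[i] < g[2])
        counts[i] <- counts[i] + 1L
      else if (sum(counts) > spec$targetGenotypes && counts[i] > g[1])
        counts[i] <- counts[i] - 1L
      i <- if (i == npop) 1L else i + 1L
    }
  }
  pops <- sprintf("P%02d", seq_len(npop))
  geno <- unlist(lapply(seq_len(npop), function(p)
    sprintf("%s_g%02d", pops[p], seq_len(counts[p]))))
  popOf <- rep(pops, counts)
  samples <- data.frame(
    population = rep(popOf, each = spec$nReplicates),
    genotype = rep(geno, each = spec$nReplicates),
    replicate = rep(seq_len(spec$nReplicates), times = length(geno)),
    stringsAsFactors = FALSE
  )
  n <- nrow(samples)
  batches <- sprintf("B%02d", seq_len(spec$nBatches))
  perm <- sample.int(n)
  assign <- rep(batches, length.out = n)[order(perm)]
  samples$batch <- assign
  # guarantee replicate spread across batches where possible
  if (spec$nBatches >= 2L && spec$nReplicates >= 2L) {
    spread <- tapply(samples$batch, samples$genotype,
                     function(b) length(unique(b)))
    if (all(spread < 2L)) {
      swap <- which(samples$genotype == samples$genotype[1L])[1:2]
      other <- setdiff(batches, samples$batch[swap[1L]])[1L]
      samples$batch[swap[2L]] <- other
    }
  }
  samples$sample_id <- sprintf("S%04d", seq_len(n))
  samples$ion_mode <- spec$ionMode
  samples$is_control <- FALSE
  if (spec$controlsPerBatch > 0) {
    ctl <- expand.grid(batch = batches,
                       idx = seq_len(spec$controlsPerBatch),
                       stringsAsFactors = FALSE)
    ctrl <- data.frame(
      population = "bulk", genotype = "bulk_control",
      replicate = seq_len(nrow(ctl)),
      batch = ctl$batch,
      sample_id = sprintf("C%03d", seq_len(nrow(ctl))),
      ion_mode = spec$ionMode,
      is_control = TRUE, stringsAsFactors = FALSE
    )
    samples <- rbind(samples, ctrl[, colnames(samples)])
  }
  rownames(samples) <- NULL
  samples[, c("sample_id", "population", "genotype", "replicate",
              "batch", "ion_mode", "is_control")]
}

#' Default metabolite configuration for the generator
#'
#' A compound panel mixing named flavonoid glycosides and alkaloids
#' (population-specific presence/absence patterns, an isomer pair split by
#' retention-time drift, a compensating isomer trio whose total is
#' invariant across populations) with unnamed filler metabolites: null
#' (uniform) compounds, strongly differential compounds, and
#' control-enriched markers that give the bulk controls a composition of
#' their own.
#'
#' @param nUnknownNull Number of uniform (null) filler metabolites.
#' @param nUnknownDifferential Number of differential filler metabolites.
#' @param nControlMarkers Number of control-enriched markers.
#' @return List understood by [simulateTruth()].
#' @export
defaultMetaboliteConfig <- function(nUnknownNull = 130,
                                    nUnknownDifferential = 15,
                                    nControlMarkers = 5) {
  named <- list(
    list(name = "K-Glc-maGlc", aglycone = "kaempferol",
         moieties = c("Glc", "maGlc"), rt = 4.15, base = 2.5e6,
         pattern = "absent_first_two", fragments = TRUE),
    list(name = "K-Glc", aglycone = "kaempferol", moieties = "Glc",
         rt = 4.04, base = 2e6, pattern = "absent_first_two",
         fragments = TRUE),
    list(name = "Q-acGlc-Rha", aglycone = "quercetin",
         moieties = c("acGlc", "Rha"), rt = 5.11, base = 4e6,
         pattern = "only_first", fragments = TRUE),
    list(name = "Q-acGlc", aglycone = "quercetin", moieties = "acGlc",
         rt = 5.59, base = 4e6, pattern = "only_first", fragments = TRUE),
    list(name = "I-acGlc-Rha", aglycone = "isorhamnetin",
         moieties = c("acGlc", "Rha"), rt = 5.46, base = 5e6,
         pattern = "only_first", fragments = TRUE),
    list(name = "I-acGlc", aglycone = "isorhamnetin", moieties = "acGlc",
         rt = 5.89, base = 4e6, pattern = "only_first", fragments = TRUE),
    list(name = "thesinine", aglycone = "thesinine", moieties = character(0),
         rt = 5.17, base = 4e6, pattern = "only_second", fragments = FALSE),
    list(name = "The-Rha", aglycone = "thesinine", moieties = "Rha",
         rt = c(4.58, 4.80), base = 3e6, pattern = "therha",
         fragments = TRUE, splitByDrift = TRUE),
    list(name = "K-Glc-feruloylGlc", aglycone = "kaempferol",
         moieties = c("Glc", "feruloylGlc"), rt = 4.40, base = 2e6,
         pattern = "variable", fragments = TRUE),
    list(name = "perloline", aglycone = "perloline",
         moieties = character(0), rt = 5.28, base = 1e6,
         pattern = "variable", fragments = FALSE, carbon = 20),
    list(name = "CGA-isomers", aglycone = "chlorogenic acid",
         moieties = character(0), rt = c(3.80, 4.06, 4.32), base = 2e6,
         pattern = "compensating", fragments = FALSE)
  )
  list(named = named,
       nUnknownNull = nUnknownNull,
       nUnknownDifferential = nUnknownDifferential,
       nControlMarkers = nControlMarkers)
}

#' Simulate the metabolite ground truth
#'
#' Builds the [TruthSet] for a design: per-metabolite formulas, adduct
#' m/z, retention times, isomer structure, per-population abundance
#' multipliers, and per-batch location, scale and retention-time-drift
#' effects. Guarantees at least one metabolite absent in a designated
#' population, at least one present in a single population only, and at
#' least one isomer pair at close retention times; isotope envelopes
#' follow the binomial model for the formula's carbon count with natural
#' 13C abundance 0.0107.
#'
#' @param spec A [designSpec()].
#' @param config Metabolite configuration (default
#'   [defaultMetaboliteConfig()]).
#' @param batchLocationSd Standard deviation of per-batch mean log-scale
#'   location shifts (default 0.5).
#' @param batchLocationPeakSd Per-metabolite deviation around the batch
#'   mean shift (default 0.15).
#' @param batchScaleSd Log-scale sd of per-batch noise scale factors
#'   (default 0.15).
#' @param maxRtDrift Largest per-batch RT offset in minutes (default
#'   0.25, enough to interleave isomers about 0.2 min apart).
#' @return A [TruthSet] (peak-level slots are filled by
#'   [renderIntensityMatrix()]).
#' @export
simulateTruth <- function(spec, config = defaultMetaboliteConfig(),
                          batchLocationSd = 0.5,
                          batchLocationPeakSd = 0.15,
                          batchScaleSd = 0.15,
                          maxRtDrift = 0.25) {
  .validateDesignSpec(spec)
  if (!length(config$named) && !config$nUnknownNull)
    stop("metabolite config is empty")
  set.seed(spec$seed + 1L)
  adduct <- ionModeAdduct(spec$ionMode)
  aglib <- aglyconeLibrary(spec$ionMode)
  molib <- moietyLibrary()
  pops <- sprintf("P%02d", seq_len(spec$nPopulations))
  npop <- length(pops)

  rows <- list()
  presence <- list()
  weights <- list()
  addMet <- function(name, formula, mz, carbon, rt, base, nIso,
                     split, frag, moieties, pattern, pres, w = NULL,
                     ctrl = NULL) {
    if (is.null(ctrl)) ctrl <- 0.5 * mean(pres)
    rows[[length(rows) + 1L]] <<- data.frame(
      metabolite_id = sprintf("M%03d", length(rows) + 1L),
      name = name, formula = formula, carbon_count = carbon,
      true_mz = mz, true_rt = rt[1L], base_intensity = base,
      n_isomer_splits = nIso,
      isomer_delta_rt = if (nIso > 1L) rt[2L] - rt[1L] else 0,
      split_by_drift = split, has_fragments = frag,
      moiety_symbols = paste(moieties, collapse = ","),
      pattern = pattern, control_presence = ctrl,
      is_differential = stats::sd(pres) > 1e-12,
      stringsAsFactors = FALSE)
    presence[[length(presence) + 1L]] <<- pres
    weights[[length(weights) + 1L]] <<-
      if (is.null(w)) matrix(1 / nIso, nIso, npop) else w
  }

  for (cmp in config$named) {
    agl <- aglib[aglib$name == cmp$aglycone, ]
    if (!is.na(agl$formula)) {
      f <- parseFormula(agl$formula)
      for (m in cmp$moieties) {
        fm <- parseFormula(molib$formula[molib$symbol == m])
        f[names(fm)] <- ifelse(is.na(f[names(fm)]), 0L,
                               f[names(fm)]) + fm
        f[is.na(f)] <- 0L
      }
      formula <- paste0(names(f)[f > 0], ifelse(f[f > 0] > 1, f[f > 0], ""),
                        collapse = "")
      mz <- adductMz(monoisotopicMass(f), adduct)
      carbon <- unname(f["C"])
    } else {
      formula <- NA_character_
      mz <- agl$referenceMz
      carbon <- cmp$carbon
    }
    nIso <- length(cmp$rt)
    pres <- switch(cmp$pattern,
      absent_first_two = c(0, 0, exp(stats::rnorm(npop - 2, 0, 0.3)))[seq_len(npop)],
      only_first = c(1, rep(0, npop - 1)),
      only_second = c(0, 1, rep(0, npop - 2))[seq_len(npop)],
      therha = c(0, 0.02, exp(stats::rnorm(npop - 2, 0, 1)))[seq_len(npop)],
      variable = exp(stats::rnorm(npop, 0, 1.2)),
      compensating = rep(1, npop),
      rep(1, npop))
    w <- NULL
    if (cmp$pattern == "compensating") {
      # isomer shares vary across populations but sum to 1: per-row
      # statistics look differential while the aggregate is invariant
      raw <- matrix(stats::runif(nIso * npop, 0.1, 1), nIso, npop)
      w <- sweep(raw, 2L, colSums(raw), "/")
    }
    addMet(cmp$name, formula, mz, carbon, cmp$rt, cmp$base, nIso,
           isTRUE(cmp$splitByDrift), cmp$fragments, cmp$moieties,
           cmp$pattern, pres, w)
  }

  nFiller <- config$nUnknownNull + config$nUnknownDifferential +
    config$nControlMarkers
  fillerKind <- c(rep("null", config$nUnknownNull),
                  rep("differential", config$nUnknownDifferential),
                  rep("control", config$nControlMarkers))
  for (i in seq_len(nFiller)) {
    c0 <- sample(8:35, 1L)
    h0 <- c0 + sample(4:20, 1L)
    o0 <- sample(2:12, 1L)
    n0 <- sample(c(0, 0, 0, 1), 1L)
    formula <- paste0("C", c0, "H", h0, if (n0) "N" else "", "O", o0)
    mz <- adductMz(monoisotopicMass(formula), adduct)
    rt <- round(stats::runif(1, 0.8, 9.5), 2)
    kind <- fillerKind[i]
    base <- if (kind == "differential")
      exp(stats::rnorm(1, log(1e6), 0.5))
    else exp(stats::rnorm(1, log(3e5), 1.2))
    pres <- switch(kind,
      null = rep(1, npop),
      differential = exp(stats::rnorm(npop, 0, 1.2)),
      control = rep(0.15, npop))
    ctrl <- if (kind == "control") 4 else NULL
    addMet(sprintf("unknown_%s_%02d", kind, i), formula, mz, c0, rt, base,
           1L, FALSE, FALSE, character(0),
           if (kind == "null") "uniform" else kind, pres, ctrl = ctrl)
  }

  met <- do.call(rbind, rows)
  presence <- do.call(rbind, presence)
  colnames(presence) <- pops
  rownames(presence) <- met$metabolite_id
  names(weights) <- met$metabolite_id

  batches <- sprintf("B%02d", seq_len(spec$nBatches))
  location <- matrix(stats::rnorm(spec$nBatches, 0, batchLocationSd),
                     spec$nBatches, nrow(met)) +
    matrix(stats::rnorm(spec$nBatches * nrow(met), 0, batchLocationPeakSd),
           spec$nBatches, nrow(met))
  dimnames(location) <- list(batches, met$metabolite_id)
  scale <- exp(stats::rnorm(spec$nBatches, 0, batchScaleSd))
  names(scale) <- batches
  rtDrift <- stats::runif(spec$nBatches, -maxRtDrift, maxRtDrift)
  names(rtDrift) <- batches

  truth <- new("TruthSet",
               metabolites = met,
               presence = presence,
               batchEffects = list(location = location, scale = scale,
                                   rtDrift = rtDrift,
                                   isomerWeights = weights),
               injectedOutliers = data.frame(sample_id = character(0),
                                             peak_id = character(0)),
               isotopePartners = data.frame(monoisotopic = character(0),
                                            plus_one = character(0),
                                            plus_two = character(0)),
               peakMap = data.frame(peak_id = character(0),
                                    metabolite_id = character(0),
                                    isomer = integer(0),
                                    role = character(0)))
  validObject(truth)
  truth
}

# expected isotopologue intensity ratios under the binomial 13C model
.isotopeRatios <- function(carbon, p = .P13C) {
  q <- p / (1 - p)
  list(m1 = carbon * q, m2 = carbon * (carbon - 1) / 2 * q^2)
}

#' Render the intensity matrix and peak annotation table
#'
#' Turns a [TruthSet] and sample design into a [PeakExperiment] plus the
#' completed truth (peak map, isotope partners, injected outliers).
#' Technical noise is multiplicative log-normal with a target replicate
#' cv; batch location/scale effects act on the log scale; per-batch RT
#' drift splits drift-affected isomer pairs into extra peak rows (one row
#' per cluster of batch-level retention times); absent metabolites are
#' rendered at a baseline noise floor; detected m/z values carry a uniform
#' relative mass error.
#'
#' @param truth A [TruthSet] from [simulateTruth()].
#' @param design Sample design from [generateDesign()] (consistent
#'   populations and batches).
#' @param noiseCv Target replicate coefficient of variation, in (0, 1)
#'   (default 0.2).
#' @param seed Integer seed for the rendering randomness.
#' @param baselineFloor Intensity floor for absent metabolites (default
#'   1e3).
#' @param massErrorPpm Half-width of the uniform per-row mass error
#'   (default 5 ppm).
#' @param bioSd Log-scale sd of genotype (clonal) biological variation
#'   (default 0.4).
#' @param rtClusterWidth Retention-time cluster diameter used to form
#'   peak rows from drifted detections (default 0.1 min).
#' @param nOutliers Number of injected replicate outlier cells (default
#'   40).
#' @param outlierFactor Multiplicative size of injected outliers (default
#'   8).
#' @param nDuplicateRows Number of duplicate detections to emit (default
#'   6).
#' @return List with `experiment` (a [PeakExperiment]) and `truth` (the
#'   completed [TruthSet]).
#' @export
renderIntensityMatrix <- function(truth, design, noiseCv = 0.2, seed = 2L,
                                  baselineFloor = 1e3, massErrorPpm = 5,
                                  bioSd = 0.4, rtClusterWidth = 0.1,
                                  nOutliers = 40, outlierFactor = 8,
                                  nDuplicateRows = 6) {
  stopifnot(noiseCv > 0, noiseCv < 1)
  met <- truth@metabolites
  presence <- truth@presence
  be <- truth@batchEffects
  pops <- colnames(presence)
  badPop <- setdiff(unique(design$population[!design$is_control]), pops)
  if (length(badPop))
    stop("design populations missing from truth: ",
         paste(badPop, collapse = ", "))
  badBatch <- setdiff(unique(design$batch), rownames(be$location))
  if (length(badBatch))
    stop("design batches missing from truth: ",
         paste(badBatch, collapse = ", "))
  set.seed(seed)
  sigma <- sqrt(log(1 + noiseCv^2))
  ns <- nrow(design)
  ctrl <- design$is_control
  popIdx <- match(design$population, pops)
  batchIdx <- match(design$batch, rownames(be$location))
  genos <- unique(design$genotype[!ctrl])
  mode <- design$ion_mode[1L]
  adduct <- ionModeAdduct(mode)

  rowsAnnot <- list()
  rowsInt <- list()
  rowsMap <- list()
  isoPartners <- list()
  addRow <- function(metId, isomer, role, mzTrue, rtApex, rtMin, rtMax,
                     values) {
    u <- stats::runif(1, -massErrorPpm, massErrorPpm)
    mzObs <- mzTrue * (1 + u * 1e-6)
    rowsAnnot[[length(rowsAnnot) + 1L]] <<- data.frame(
      peak_id = NA_character_, mz = mzObs, rt = rtApex,
      rtmin = rtMin, rtmax = rtMax,
      mzmin = mzObs - .ppmWindow(mzObs, massErrorPpm),
      mzmax = mzObs + .ppmWindow(mzObs, massErrorPpm),
      ion_mode = mode, adduct = "unknown", isotope_links = "",
      stringsAsFactors = FALSE)
    rowsInt[[length(rowsInt) + 1L]] <<- values
    rowsMap[[length(rowsMap) + 1L]] <<- data.frame(
      peak_id = NA_character_, metabolite_id = metId, isomer = isomer,
      role = role, stringsAsFactors = FALSE)
    length(rowsAnnot)
  }
  floorNoise <- function(n) {
    eps <- pmin(pmax(stats::rnorm(n, 0, 0.25), -0.5), 0.5)
    baselineFloor * exp(eps)
  }

  for (mi in seq_len(nrow(met))) {
    m <- met[mi, ]
    w <- be$isomerWeights[[m$metabolite_id]]
    genoMult <- stats::setNames(exp(stats::rnorm(length(genos), 0, bioSd)),
                                genos)
    presSample <- ifelse(ctrl, m$control_presence,
                         presence[mi, popIdx])
    gm <- ifelse(ctrl, 1, genoMult[design$genotype])
    nIso <- m$n_isomer_splits
    isoRts <- m$true_rt + (seq_len(nIso) - 1L) *
      (if (nIso > 1L) m$isomer_delta_rt else 0)
    ratios <- .isotopeRatios(m$carbon_count)

    isoValues <- matrix(NA_real_, nIso, ns)
    for (ii in seq_len(nIso)) {
      mu <- m$base_intensity * presSample * w[ii, ifelse(ctrl, 1L, popIdx)] * gm
      # control weight: controls take the population-average isomer share
      if (any(ctrl)) mu[ctrl] <- m$base_intensity * presSample[ctrl] *
          mean(w[ii, ]) * gm[ctrl]
      eps <- stats::rnorm(ns, 0, sigma * be$scale[batchIdx])
      vals <- ifelse(mu > 0,
                     exp(log(mu) + be$location[cbind(batchIdx, mi)] + eps),
                     floorNoise(ns))
      isoValues[ii, ] <- vals
    }

    if (m$split_by_drift && nIso > 1L) {
      det <- expand.grid(isomer = seq_len(nIso),
                         batch = seq_along(be$rtDrift))
      det$rt <- isoRts[det$isomer] + be$rtDrift[det$batch]
      cl <- stats::cutree(stats::hclust(stats::dist(det$rt), "complete"),
                          h = rtClusterWidth)
      for (cid in sort(unique(cl))) {
        sel <- which(cl == cid)
        vals <- floorNoise(ns)
        for (d in sel) {
          inCell <- batchIdx == det$batch[d]
          vals[inCell] <- pmax(vals[inCell],
                               isoValues[det$isomer[d], inCell])
        }
        rts <- det$rt[sel]
        addRow(m$metabolite_id, det$isomer[sel][1L], "mono", m$true_mz,
               round(mean(rts), 2), min(rts) - 0.05, max(rts) + 0.05, vals)
      }
      # fragments attach to the undrifted isomer apexes
      if (m$has_fragments)
        .addFragmentRows(m, isoRts, isoValues, adduct, addRow)
      next
    }

    for (ii in seq_len(nIso)) {
      vals <- isoValues[ii, ]
      rowId <- addRow(m$metabolite_id, ii, "mono", m$true_mz,
                      round(isoRts[ii], 2), isoRts[ii] - 0.05,
                      isoRts[ii] + 0.05, vals)
      # isotope envelope
      if (ratios$m1 * m$base_intensity >= 2 * baselineFloor) {
        v1 <- vals * ratios$m1 * exp(stats::rnorm(ns, 0, 0.03))
        r1 <- addRow(m$metabolite_id, ii, "M+1",
                     m$true_mz + .ISOTOPE_SPACING, round(isoRts[ii], 2),
                     isoRts[ii] - 0.05, isoRts[ii] + 0.05, v1)
        r2 <- NA_integer_
        if (ratios$m2 * m$base_intensity >= 2 * baselineFloor) {
          v2 <- vals * ratios$m2 * exp(stats::rnorm(ns, 0, 0.03))
          r2 <- addRow(m$metabolite_id, ii, "M+2",
                       m$true_mz + 2 * .ISOTOPE_SPACING,
                       round(isoRts[ii], 2), isoRts[ii] - 0.05,
                       isoRts[ii] + 0.05, v2)
        }
        isoPartners[[length(isoPartners) + 1L]] <-
          c(mono = rowId, plus_one = r1, plus_two = r2)
      }
    }
    if (m$has_fragments)
      .addFragmentRows(m, isoRts, isoValues, adduct, addRow)
  }

  annot <- do.call(rbind, rowsAnnot)
  x <- do.call(rbind, rowsInt)
  map <- do.call(rbind, rowsMap)

  # duplicate detections of a few well-behaved rows (merge-stage fodder)
  monoIdx <- which(map$role == "mono" &
                     met$pattern[match(map$metabolite_id,
                                       met$metabolite_id)] == "uniform")
  dupFrom <- utils::head(monoIdx, nDuplicateRows)
  for (d in dupFrom) {
    nr <- nrow(annot) + 1L
    annot <- rbind(annot, annot[d, ])
    annot$mz[nr] <- annot$mz[d] * (1 + 3e-6)
    annot$rt[nr] <- annot$rt[d] + 0.02
    annot$rtmin[nr] <- annot$rtmin[d]
    annot$rtmax[nr] <- annot$rtmax[d] + 0.02
    x <- rbind(x, x[d, ] * 0.85)
    map <- rbind(map, data.frame(peak_id = NA_character_,
                                 metabolite_id = map$metabolite_id[d],
                                 isomer = map$isomer[d],
                                 role = "duplicate"))
  }

  # peak ids (nudge rt until unique if rounding collides)
  ids <- formatPeakId(annot$ion_mode, annot$mz, annot$rt)
  while (anyDuplicated(ids)) {
    d <- which(duplicated(ids))
    annot$rt[d] <- annot$rt[d] + 0.01
    annot$rtmax[d] <- pmax(annot$rtmax[d], annot$rt[d])
    ids <- formatPeakId(annot$ion_mode, annot$mz, annot$rt)
  }
  annot$peak_id <- ids
  map$peak_id <- ids

  # record isotope partner links in the annotation table
  ip <- if (length(isoPartners)) {
    ipm <- do.call(rbind, isoPartners)
    data.frame(monoisotopic = ids[ipm[, "mono"]],
               plus_one = ids[ipm[, "plus_one"]],
               plus_two = ifelse(is.na(ipm[, "plus_two"]), NA_character_,
                                 ids[ipm[, "plus_two"]]),
               stringsAsFactors = FALSE)
  } else data.frame(monoisotopic = character(0), plus_one = character(0),
                    plus_two = character(0))
  link <- ifelse(is.na(ip$plus_two), ip$plus_one,
                 paste(ip$plus_one, ip$plus_two, sep = ","))
  annot$isotope_links[match(ip$monoisotopic, ids)] <- link

  # inject replicate outliers into uniform filler rows
  outCells <- data.frame(sample_id = character(0), peak_id = character(0))
  mapName <- met$name[match(map$metabolite_id, met$metabolite_id)]
  eligible <- which(map$role == "mono" & grepl("^unknown_null", mapName))
  expCols <- which(!ctrl)
  if (nOutliers > 0 && length(eligible)) {
    pickRow <- sample(eligible, nOutliers, replace = TRUE)
    pickCol <- sample(expCols, nOutliers, replace = TRUE)
    keep <- !duplicated(cbind(pickRow, pickCol))
    pickRow <- pickRow[keep]; pickCol <- pickCol[keep]
    x[cbind(pickRow, pickCol)] <- x[cbind(pickRow, pickCol)] * outlierFactor
    outCells <- data.frame(sample_id = design$sample_id[pickCol],
                           peak_id = ids[pickRow],
                           stringsAsFactors = FALSE)
  }

  pe <- PeakExperiment(x, annot, design)
  truthOut <- new("TruthSet", metabolites = met, presence = presence,
                  batchEffects = be, injectedOutliers = outCells,
                  isotopePartners = ip, peakMap = map)
  validObject(truthOut)
  list(experiment = pe, truth = truthOut)
}

# fragment ion rows for a glycoside: successive neutral losses from the
# parent, rendered proportional to the parent so they co-elute and
# correlate
.addFragmentRows <- function(m, isoRts, isoValues, adduct, addRow) {
  losses <- strsplit(m$moiety_symbols, ",")[[1L]]
  if (!length(losses)) return(invisible())
  molib <- moietyLibrary()
  lossMass <- molib$lossMass[match(rev(losses), molib$symbol)]
  rel <- c(0.45, 0.25, 0.12)
  ns <- ncol(isoValues)
  for (ii in seq_len(nrow(isoValues))) {
    mzCur <- m$true_mz
    for (li in seq_along(lossMass)) {
      mzCur <- mzCur - lossMass[li]
      vals <- isoValues[ii, ] * rel[min(li, length(rel))] *
        exp(stats::rnorm(ns, 0, 0.05))
      addRow(m$metabolite_id, ii, "fragment", mzCur,
             round(isoRts[ii], 2), isoRts[ii] - 0.05, isoRts[ii] + 0.05,
             vals)
    }
  }
  invisible()
}

#' Render pseudo mass spectra for annotated truth metabolites
#'
#' Emits one spectral record per glycoside/alkaloid metabolite: the
#' (de)protonated parent ion and fragment ions at the parent minus
#' successive neutral losses, with configurable relative intensities.
#' Aglycone-only metabolites yield single-ion spectra.
#'
#' @param truth A [TruthSet].
#' @param relIntensities Relative fragment intensities, parent first
#'   (default `c(100, 45, 25, 12)` recycled as needed).
#' @return List of spectra in the shape accepted by [writeMsp()].
#' @export
renderPseudoSpectra <- function(truth, relIntensities = c(100, 45, 25, 12)) {
  met <- truth@metabolites
  molib <- moietyLibrary()
  named <- met[!grepl("^unknown", met$name), , drop = FALSE]
  lapply(seq_len(nrow(named)), function(i) {
    m <- named[i, ]
    losses <- strsplit(m$moiety_symbols, ",")[[1L]]
    mzs <- m$true_mz
    if (length(losses)) {
      lossMass <- molib$lossMass[match(rev(losses), molib$symbol)]
      mzs <- c(mzs, m$true_mz - cumsum(lossMass))
    }
    rel <- relIntensities[pmin(seq_along(mzs), length(relIntensities))]
    list(name = m$name, precursorMz = m$true_mz,
         ions = data.frame(mz = mzs, intensity = rel))
  })
}
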