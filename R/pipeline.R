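# End-to-end orchestration: simulate -> qc -> deisotope -> stats ->
# aggregate -> annotate, as a configured, logged, reproducible run.

#' Build a pipeline run configuration
#'
#' All stage parameters with their defaults; any can be overridden. The
#' resolved configuration is serialised verbatim into the run directory,
#' so a run can be reproduced from its output alone.
#'
#' @param outDir Run directory to create.
#' @param seed Global seed.
#' @param stages Character vector of stages to run, in fixed order; a
#'   subset of `c("simulate", "qc", "deisotope", "stats", "aggregate",
#'   "annotate")`.
#' @param peakTable,sampleMeta Input paths (required when `"simulate"` is
#'   not among the stages).
#' @param ionMode `"positive"` or `"negative"`.
#' @param ... Overrides of stage parameters: `ppmTol`, `rtTol`,
#'   `alphaBatch`, `alphaInvariance`, `cvTrigger`, `zThreshold`, `rMin`,
#'   `ratioMin`, `fdrAlpha`, `intensityMin`, `topK`, `noiseCv`,
#'   `aggregateMz`, `aggregatePpm`, `aggregateRtRange`.
#' @return List of class `runConfig`.
#' @export
runConfig <- function(outDir, seed = 1L,
                      stages = c("simulate", "qc", "deisotope", "stats",
                                 "aggregate", "annotate"),
                      peakTable = NULL, sampleMeta = NULL,
                      ionMode = "positive", ...) {
  cfg <- list(
    outDir = outDir, seed = as.integer(seed),
    stages = stages, peakTable = peakTable, sampleMeta = sampleMeta,
    ionMode = ionMode,
    ppmTol = 20, rtTol = 0.2,
    alphaBatch = 0.05, alphaInvariance = 0.05,
    cvTrigger = 0.2, zThreshold = 3.0, cvThreshold = 0.3,
    rMin = 0.9, ratioMin = 2.0,
    fdrAlpha = 0.01, intensityMin = 1e5, topK = 50,
    noiseCv = 0.2, preset = "fast",
    aggregateMz = NULL, aggregatePpm = 10, aggregateRtRange = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  badStage <- setdiff(stages, c("simulate", "qc", "deisotope", "stats",
                                "aggregate", "annotate"))
  if (length(badStage))
    stop("unknown stages: ", paste(badStage, collapse = ", "))
  if (!"simulate" %in% stages &&
      (is.null(peakTable) || is.null(sampleMeta)))
    stop("without the simulate stage, peakTable and sampleMeta are required")
  class(cfg) <- "runConfig"
  cfg
}

#' Run the metabotyping pipeline
#'
#' Executes the configured stages in fixed order (simulate, qc,
#' deisotope, stats, aggregate, annotate), writing every artifact to the
#' run directory: peak tables after each stage, the QC report (peaks in
#' and out per filter, with the criterion applied), the CV report, the
#' isotope group table, differential results and the ranked top peaks,
#' population profiles with the UPGMA tree in Newick format, aggregate
#' results, annotations with an MSP library, the resolved configuration
#' and a structured log. Identical configuration and seed give identical
#' outputs. Disabling qc while running stats proceeds on the raw table
#' with a logged warning.
#'
#' @param config A [runConfig()].
#' @return Invisibly, a list with the run directory, final
#'   [PeakExperiment], per-stage peak counts and (for simulated runs) the
#'   [TruthSet].
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(config$outDir, "run.log")
  logLines <- character(0)
  logMsg <- function(...) {
    line <- paste0(...)
    logLines <<- c(logLines, line)
    message(line)
  }
  yaml::write_yaml(unclass(config), file.path(config$outDir, "config.yaml"))
  counts <- list()
  truth <- NULL

  runStage <- function(stage, expr) {
    logMsg("[", stage, "] starting")
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("simulate" %in% config$stages) {
    pe <- runStage("simulate", {
      spec <- designSpec(preset = config$preset, ionMode = config$ionMode,
                         seed = config$seed)
      design <- generateDesign(spec)
      truth <- simulateTruth(spec)
      rendered <- renderIntensityMatrix(truth, design,
                                        noiseCv = config$noiseCv,
                                        seed = config$seed + 1L)
      truth <- rendered$truth
      writePeakTable(rendered$experiment,
                     file.path(config$outDir, "peaks_raw.tsv"))
      writeSampleMeta(rendered$experiment,
                      file.path(config$outDir, "samples.tsv"))
      rendered$experiment
    })
  } else {
    pe <- runStage("load", {
      meta <- readSampleMeta(config$sampleMeta)
      readPeakTable(config$peakTable, meta)
    })
  }
  counts$input <- nrow(pe)
  logMsg("[input] ", nrow(pe), " peaks x ", ncol(pe), " samples")

  if ("qc" %in% config$stages) {
    pe <- runStage("qc", {
      pe <- mergeDuplicatePeaks(pe, ppmTol = config$ppmTol,
                                rtTol = config$rtTol)
      pe <- correctBatchEffects(pe)
      pe <- filterResidualBatch(pe, alpha = config$alphaBatch)
      pe <- removeReplicateOutliers(pe, cvTrigger = config$cvTrigger,
                                    zThreshold = config$zThreshold)
      pe <- filterInvariantPeaks(pe, alpha = config$alphaInvariance)
      cv <- replicateCv(pe, cvThreshold = config$cvThreshold)
      utils::write.csv(
        data.frame(peak_id = rownames(intensities(pe)),
                   median_cv = cv$medianCv),
        file.path(config$outDir, "cv_report.csv"), row.names = FALSE)
      pca <- pcaQc(pe)
      utils::write.csv(
        cbind(pca$samples[, c("sample_id", "population", "is_control")],
              as.data.frame(pca$scores)),
        file.path(config$outDir, "pca_scores.csv"), row.names = FALSE)
      for (rec in qcLog(pe))
        logMsg("[qc] ", rec$stage, ": ", rec$peaks_in, " -> ",
               rec$peaks_out, " (", rec$criterion, ")")
      writePeakTable(pe, file.path(config$outDir, "peaks_qc.tsv"))
      pe
    })
    counts$qc <- nrow(pe)
  } else if (any(c("stats", "aggregate", "annotate") %in% config$stages)) {
    logMsg("[qc] WARNING: qc disabled; downstream stages run on the raw table")
  }

  if ("deisotope" %in% config$stages) {
    pe <- runStage("deisotope", {
      groups <- findIsotopeGroups(pe, ppmTol = config$ppmTol,
                                  rtTol = config$rtTol,
                                  rMin = config$rMin,
                                  ratioMin = config$ratioMin)
      utils::write.csv(groups,
                       file.path(config$outDir, "isotope_groups.csv"),
                       row.names = FALSE)
      pe2 <- deisotope(pe, groups)
      logMsg("[deisotope] ", nrow(pe), " -> ", nrow(pe2), " peaks (",
             nrow(groups), " envelopes)")
      writePeakTable(pe2, file.path(config$outDir, "peaks_deisotoped.tsv"))
      pe2
    })
    counts$deisotope <- nrow(pe)
  }

  topRanked <- NULL
  if ("stats" %in% config$stages) {
    topRanked <- runStage("stats", {
      res <- moderatedPopulationTest(pe)
      utils::write.csv(res, file.path(config$outDir, "diff_results.csv"),
                       row.names = FALSE)
      top <- rankTopPeaks(res, intensityMin = config$intensityMin,
                          k = config$topK)
      top$ranking_statistic <- "moderated F within intensity gate"
      utils::write.csv(top, file.path(config$outDir, "top_peaks.csv"),
                       row.names = FALSE)
      prof <- populationProfiles(pe)
      utils::write.csv(as.data.frame(prof$matrix),
                       file.path(config$outDir, "population_profiles.csv"))
      if (ncol(prof$matrix) >= 2L)
        writeNewick(upgmaTree(prof),
                    file.path(config$outDir, "populations_upgma.nwk"))
      logMsg("[stats] ", sum(res$p_adjust < config$fdrAlpha, na.rm = TRUE),
             " peaks at FDR < ", config$fdrAlpha, "; top ", nrow(top),
             " ranked")
      top
    })
  }

  if ("aggregate" %in% config$stages && !is.null(config$aggregateMz)) {
    runStage("aggregate", {
      agg <- aggregateIsomericPeaks(pe, targetMz = config$aggregateMz,
                                    ppmWindow = config$aggregatePpm,
                                    rtRange = config$aggregateRtRange)
      utils::write.csv(data.frame(sample_id = names(agg$aggregate),
                                  aggregate = agg$aggregate),
                       file.path(config$outDir, "aggregate.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(target_mz = agg$targetMz, ppm_window = agg$ppmWindow,
             members = agg$members, F = agg$F, p = agg$p),
        file.path(config$outDir, "aggregate_ftest.json"),
        auto_unbox = TRUE, digits = NA)
      logMsg("[aggregate] ", length(agg$members), " member peaks; F p = ",
             signif(agg$p, 3))
    })
  }

  if ("annotate" %in% config$stages) {
    runStage("annotate", {
      seeds <- if (!is.null(topRanked)) topRanked$peak_id
               else rowData(pe)$peak_id
      ann <- annotatePeaks(pe, seeds, ppmTol = config$ppmTol,
                           rMin = config$rMin)
      utils::write.csv(ann$table,
                       file.path(config$outDir, "annotations.csv"),
                       row.names = FALSE)
      if (length(ann$spectra))
        writeMsp(ann$spectra,
                 file.path(config$outDir, "annotated_spectra.msp"))
      logMsg("[annotate] ", sum(!is.na(ann$table$name)), " of ",
             nrow(ann$table), " peaks annotated")
    })
  }

  qcJson <- list(seed = config$seed, stages = config$stages,
                 peak_counts = counts,
                 qc_log = lapply(qcLog(pe), function(rec)
                   rec[intersect(names(rec),
                                 c("stage", "peaks_in", "peaks_out",
                                   "criterion"))]))
  jsonlite::write_json(qcJson, file.path(config$outDir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(logLines, logFile)
  invisible(list(outDir = config$outDir, experiment = pe,
                 peakCounts = counts, truth = truth,
                 topRanked = topRanked))
}

#' Annotate a set of peaks against the built-in libraries
#'
#' For each seed peak: the isotopic-presence check, the co-eluting
#' correlated group (fragment candidates), and greedy neutral-loss
#' decomposition of the seed as parent with the co-eluting ions as
#' fragments.
#'
#' @param pe A [PeakExperiment].
#' @param peakIds Seed peak ids (default: all).
#' @param ppmTol Mass tolerance in ppm (default 20).
#' @param rMin Co-elution correlation threshold (default 0.9).
#' @param rtTol Co-elution window in minutes (default 0.05).
#' @return List with `table` (one row per seed: name, aglycone, moieties,
#'   evidence flags, residual ppm) and `spectra` (MSP-ready records for
#'   annotated peaks).
#' @export
annotatePeaks <- function(pe, peakIds = NULL, ppmTol = 20, rMin = 0.9,
                          rtTol = 0.05) {
  rd <- rowData(pe)
  if (is.null(peakIds)) peakIds <- rd$peak_id
  ionMode <- rd$ion_mode[1L]
  if (is.null(ionMode) || is.na(ionMode)) ionMode <- "positive"
  adduct <- ionModeAdduct(ionMode)
  x <- intensities(pe)
  rows <- list()
  spectra <- list()
  for (pid in peakIds) {
    i <- match(pid, rd$peak_id)
    if (is.na(i)) next
    iso <- checkIsotopicPresence(pe, pid, ppmTol = ppmTol)
    group <- suppressMessages(
      coelutingGroup(pe, pid, rMin = rMin, rtTol = rtTol))
    fragIds <- setdiff(group, pid)
    fragMz <- rd$mz[match(fragIds, rd$peak_id)]
    below <- fragMz < rd$mz[i]
    fragIds <- fragIds[below]
    fragMz <- fragMz[below]
    ann <- annotateGlycoside(rd$mz[i], fragMz, adduct = adduct,
                             ppmTol = ppmTol)
    rows[[length(rows) + 1L]] <- data.frame(
      peak_id = pid,
      name = ann$name,
      aglycone = ann$aglycone,
      ambiguous_aglycones = paste(ann$ambiguousAglycones, collapse = "/"),
      moieties = paste(ann$moietySymbols, collapse = ","),
      isotopic_presence = iso$passed,
      n_coeluting = length(group),
      residual_ppm = ann$residualPpm,
      stringsAsFactors = FALSE)
    if (!is.na(ann$name)) {
      relInt <- if (length(fragIds))
        rowMeans(x[match(fragIds, rd$peak_id), , drop = FALSE],
                 na.rm = TRUE) / max(mean(x[i, ], na.rm = TRUE), 1e-9)
      else numeric(0)
      ord <- order(-fragMz)
      spectra[[length(spectra) + 1L]] <- list(
        name = paste0(ann$name, " (", pid, ")"),
        precursorMz = rd$mz[i],
        ions = data.frame(
          mz = c(rd$mz[i], fragMz[ord]),
          intensity = round(100 * c(1, relInt[ord]), 2)))
    }
  }
  list(table = do.call(rbind, rows), spectra = spectra)
}
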