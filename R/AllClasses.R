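# Central data containers.

#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#'   rowData<- colData<-
NULL

.PEAK_COLS <- c("peak_id", "mz", "rt", "rtmin", "rtmax")
.SAMPLE_COLS <- c("sample_id", "population", "genotype", "replicate",
                  "batch", "ion_mode", "is_control")

#' PeakExperiment: an annotated LC-MS peak table
#'
#' A \linkS4class{SummarizedExperiment} holding a peaks-by-samples intensity
#' matrix (assay `"intensity"`), the peak annotation table as `rowData`
#' (detected m/z, retention time, m/z and RT ranges, ion mode, adduct and
#' isotopic-partner links) and the sample metadata as `colData` (population,
#' genotype, clonal replicate, analytical batch, ion mode, control flag).
#' Every pipeline stage consumes and returns this class.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @aliases PeakExperiment-class
#' @exportClass PeakExperiment
setClass("PeakExperiment", contains = "SummarizedExperiment")

setValidity("PeakExperiment", function(object) {
  msg <- character(0)
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  rd <- rowData(object)
  cd <- colData(object)
  miss <- setdiff(.PEAK_COLS, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste("missing peak annotation columns:",
                        paste(miss, collapse = ", ")))
  missc <- setdiff(.SAMPLE_COLS, colnames(cd))
  if (length(missc))
    msg <- c(msg, paste("missing sample metadata columns:",
                        paste(missc, collapse = ", ")))
  if (!length(msg)) {
    if (anyDuplicated(rd$peak_id))
      msg <- c(msg, "duplicate peak_id")
    if (anyDuplicated(cd$sample_id))
      msg <- c(msg, "duplicate sample_id")
    x <- SummarizedExperiment::assay(object, "intensity")
    if (any(x < 0, na.rm = TRUE))
      msg <- c(msg, "negative intensities")
    bad <- !is.na(rd$rt) & (rd$rt < rd$rtmin - 1e-9 | rd$rt > rd$rtmax + 1e-9)
    if (any(bad))
      msg <- c(msg, "rt outside [rtmin, rtmax] for some peaks")
    reps <- cd[!cd$is_control, c("genotype", "replicate")]
    if (nrow(reps) && anyDuplicated(paste(reps$genotype, reps$replicate)))
      msg <- c(msg, "(genotype, replicate) not unique among non-controls")
    if (any(is.na(cd$batch)))
      msg <- c(msg, "every sample needs a batch")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeakExperiment
#'
#' @param intensity Numeric peaks-by-samples matrix; `NA` marks missing
#'   (removed) measurements, all other values must be nonnegative.
#' @param peaks `data.frame` of peak annotations; must contain `peak_id`,
#'   `mz`, `rt`, `rtmin`, `rtmax` (extra columns such as `mzmin`, `mzmax`,
#'   `ion_mode`, `adduct`, `isotope_links` are kept).
#' @param samples `data.frame` of sample metadata with columns `sample_id`,
#'   `population`, `genotype`, `replicate`, `batch`, `ion_mode`,
#'   `is_control`.
#' @return A `PeakExperiment`.
#' @export
PeakExperiment <- function(intensity, peaks, samples) {
  intensity <- as.matrix(intensity)
  peaks <- DataFrame(peaks)
  samples <- DataFrame(samples)
  rownames(peaks) <- peaks$peak_id
  rownames(samples) <- samples$sample_id
  rownames(intensity) <- peaks$peak_id
  colnames(intensity) <- samples$sample_id
  se <- SummarizedExperiment(assays = list(intensity = intensity),
                             rowData = peaks, colData = samples)
  new("PeakExperiment", se)
}

#' @describeIn PeakExperiment Intensity matrix accessor.
#' @param object,x A `PeakExperiment`.
#' @export
intensities <- function(x) SummarizedExperiment::assay(x, "intensity")

#' @describeIn PeakExperiment Peak annotation table as a `data.frame`.
#' @export
peakData <- function(x) as.data.frame(rowData(x))

#' @describeIn PeakExperiment Sample metadata as a `data.frame`.
#' @export
sampleData <- function(x) as.data.frame(colData(x))

#' @describeIn PeakExperiment Peak m/z values, named by peak id.
#' @export
peakMz <- function(x) stats::setNames(rowData(x)$mz, rowData(x)$peak_id)

#' @describeIn PeakExperiment Peak apex retention times (minutes), named by
#'   peak id.
#' @export
peakRt <- function(x) stats::setNames(rowData(x)$rt, rowData(x)$peak_id)

setMethod("show", "PeakExperiment", function(object) {
  cd <- colData(object)
  cat("PeakExperiment:", nrow(object), "peaks x", ncol(object), "samples\n")
  cat("  populations:", length(unique(cd$population[!cd$is_control])),
      " genotypes:", length(unique(cd$genotype[!cd$is_control])),
      " batches:", length(unique(cd$batch)),
      " controls:", sum(cd$is_control), "\n")
  if (length(metadata(object)$qc_log))
    cat("  QC stages applied:",
        paste(vapply(metadata(object)$qc_log, `[[`, "", "stage"),
              collapse = " -> "), "\n")
})

# append a structured stage record to the QC log carried in metadata()
.logStage <- function(pe, stage, nIn, nOut, detail = list()) {
  log <- metadata(pe)$qc_log
  if (is.null(log)) log <- list()
  log[[length(log) + 1L]] <- c(list(stage = stage, peaks_in = nIn,
                                    peaks_out = nOut), detail)
  metadata(pe)$qc_log <- log
  pe
}

#' QC log of a PeakExperiment
#'
#' Each pipeline stage appends a record of peaks in, peaks out and the
#' criterion applied.
#'
#' @param x A `PeakExperiment`.
#' @return List of per-stage records.
#' @export
qcLog <- function(x) metadata(x)$qc_log

#' TruthSet: ground truth of a synthetic experiment
#'
#' Produced by [simulateTruth()] and completed by [renderIntensityMatrix()].
#' Holds the simulated metabolites (formulas, adduct m/z, retention times,
#' per-population abundance multipliers, isomer splits), the injected batch
#' location/scale/RT-drift effects, injected replicate outliers, the
#' isotope-partner map, and the mapping from rendered peak rows back to
#' metabolites — everything recovery tests score against.
#'
#' @slot metabolites `data.frame`, one row per simulated metabolite.
#' @slot presence numeric matrix metabolites x populations of abundance
#'   multipliers (0 = absent).
#' @slot batchEffects list with `location` (batch x metabolite log-scale
#'   shifts), `scale` (per-batch noise scale factors) and `rtDrift`
#'   (per-batch RT offsets, minutes).
#' @slot injectedOutliers `data.frame` with `sample_id`, `peak_id`.
#' @slot isotopePartners `data.frame` with `monoisotopic`, `plus_one`,
#'   `plus_two` peak ids.
#' @slot peakMap `data.frame` mapping `peak_id` to `metabolite_id`, isomer
#'   index and role (`"mono"`, `"M+1"`, `"M+2"`, `"fragment"`,
#'   `"duplicate"`).
#' @aliases TruthSet-class
#' @exportClass TruthSet
setClass("TruthSet", representation(
  metabolites = "data.frame",
  presence = "matrix",
  batchEffects = "list",
  injectedOutliers = "data.frame",
  isotopePartners = "data.frame",
  peakMap = "data.frame"
))

setValidity("TruthSet", function(object) {
  msg <- character(0)
  met <- object@metabolites
  if (!all(c("metabolite_id", "formula", "carbon_count", "true_mz",
             "true_rt", "base_intensity", "n_isomer_splits") %in%
           colnames(met)))
    msg <- c(msg, "metabolites table incomplete")
  if (nrow(met) && nrow(object@presence) != nrow(met))
    msg <- c(msg, "presence matrix must have one row per metabolite")
  if (any(object@presence < 0))
    msg <- c(msg, "presence multipliers must be >= 0")
  if (nrow(met) && any(met$n_isomer_splits < 1))
    msg <- c(msg, "n_isomer_splits must be >= 1")
  if (length(object@batchEffects)) {
    if (any(object@batchEffects$scale <= 0))
      msg <- c(msg, "batch scale factors must be > 0")
  }
  ip <- object@isotopePartners
  if (nrow(ip) && nrow(object@peakMap)) {
    known <- object@peakMap$peak_id
    ref <- c(ip$monoisotopic, ip$plus_one, ip$plus_two)
    if (!all(ref[!is.na(ref)] %in% known))
      msg <- c(msg, "isotope partners reference unknown peaks")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TruthSet Metabolite truth table.
#' @param x A `TruthSet`.
#' @export
truthMetabolites <- function(x) x@metabolites

#' @describeIn TruthSet Metabolite-by-population abundance multipliers.
#' @export
truthPresence <- function(x) x@presence

#' @describeIn TruthSet Injected batch effects (location, scale, RT drift).
#' @export
truthBatchEffects <- function(x) x@batchEffects

#' @describeIn TruthSet Injected replicate outlier cells.
#' @export
truthOutliers <- function(x) x@injectedOutliers

#' @describeIn TruthSet Isotope partner map ([M], [M+1], [M+2] peak ids).
#' @export
truthIsotopePartners <- function(x) x@isotopePartners

#' @describeIn TruthSet Rendered peak row to metabolite map.
#' @export
truthPeakMap <- function(x) x@peakMap

setMethod("show", "TruthSet", function(object) {
  met <- object@metabolites
  cat("TruthSet:", nrow(met), "metabolites,",
      sum(met$is_differential), "differential,",
      nrow(object@peakMap), "rendered peak rows\n")
  cat("  isotope triples:", nrow(object@isotopePartners),
      " injected outliers:", nrow(object@injectedOutliers), "\n")
})
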