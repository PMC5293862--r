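# Delimited-text interchange: peak tables (annotation columns + one
# column per sample) and sample metadata.

.ANNOT_IO_COLS <- c("peak_id", "mz", "rt", "rtmin", "rtmax", "mzmin",
                    "mzmax", "ion_mode", "adduct", "isotope_links")

#' Write a peak table to delimited text
#'
#' One row per peak: the annotation columns (`peak_id`, `mz`, `rt`,
#' `rtmin`, `rtmax`, `mzmin`, `mzmax`, `ion_mode`, `adduct`,
#' `isotope_links`) followed by one intensity column per sample.
#'
#' @param pe A [PeakExperiment].
#' @param file Path to write (tab-separated).
#' @return The file path, invisibly.
#' @export
writePeakTable <- function(pe, file) {
  rd <- peakData(pe)
  for (col in .ANNOT_IO_COLS)
    if (!col %in% colnames(rd))
      rd[[col]] <- if (col %in% c("adduct", "isotope_links"))
        "" else NA_real_
  tab <- cbind(rd[, .ANNOT_IO_COLS, drop = FALSE],
               as.data.frame(intensities(pe)))
  utils::write.table(tab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write sample metadata to delimited text
#'
#' @param pe A [PeakExperiment] or a sample metadata `data.frame`.
#' @param file Path to write (tab-separated).
#' @return The file path, invisibly.
#' @export
writeSampleMeta <- function(pe, file) {
  meta <- if (is(pe, "PeakExperiment")) sampleData(pe) else pe
  utils::write.table(meta[, .SAMPLE_COLS], file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read sample metadata from delimited text
#'
#' @param file Path to a tab-separated file written by
#'   [writeSampleMeta()] (or matching its columns).
#' @return Sample metadata `data.frame`.
#' @export
readSampleMeta <- function(file) {
  meta <- utils::read.delim(file, stringsAsFactors = FALSE)
  miss <- setdiff(.SAMPLE_COLS, colnames(meta))
  if (length(miss))
    stop("sample metadata missing columns: ", paste(miss, collapse = ", "))
  meta$is_control <- as.logical(meta$is_control)
  meta$batch <- as.character(meta$batch)
  meta
}

#' Read a peak table from delimited text
#'
#' @param file Path to a tab-separated peak table written by
#'   [writePeakTable()].
#' @param meta Sample metadata `data.frame` (from [readSampleMeta()]).
#' @return A [PeakExperiment].
#' @export
readPeakTable <- function(file, meta) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                           check.names = FALSE)
  miss <- setdiff(c("peak_id", "mz", "rt", "rtmin", "rtmax"),
                  colnames(tab))
  if (length(miss))
    stop("peak table missing columns: ", paste(miss, collapse = ", "))
  annotCols <- intersect(.ANNOT_IO_COLS, colnames(tab))
  sampleCols <- setdiff(colnames(tab), annotCols)
  missing <- setdiff(meta$sample_id, sampleCols)
  if (length(missing))
    stop("peak table lacks intensity columns for samples: ",
         paste(utils::head(missing, 5), collapse = ", "))
  x <- as.matrix(tab[, as.character(meta$sample_id), drop = FALSE])
  annot <- tab[, annotCols, drop = FALSE]
  if ("isotope_links" %in% colnames(annot))
    annot$isotope_links[is.na(annot$isotope_links)] <- ""
  PeakExperiment(x, annot, meta)
}
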