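# Duplicate-peak merging.
#
# Split detection of a single chromatographic peak leaves near-identical
# rows in the aligned table; rows whose m/z agree within a ppm window and
# whose apex retention times agree within an RT tolerance are collapsed to
# one row, retaining the per-sample maximum.

#' Merge duplicate peak rows
#'
#' Peaks are grouped transitively: any pair with `|dmz| <= ppmTol` (relative
#' to the smaller m/z) and `|drt| <= rtTol` joins the same group. Each group
#' collapses to a single row carrying the per-sample maximum intensity and
#' the intensity-weighted representative annotation (the member with the
#' highest mean intensity). A merge log is recorded in the QC log.
#'
#' @param pe A [PeakExperiment].
#' @param ppmTol m/z tolerance in ppm (default 20).
#' @param rtTol Retention-time tolerance in minutes (default 0.2).
#' @return A `PeakExperiment` with duplicates merged.
#' @export
mergeDuplicatePeaks <- function(pe, ppmTol = 20, rtTol = 0.2) {
  n <- nrow(pe)
  if (n == 0L)
    return(.logStage(pe, "merge_duplicates", 0L, 0L,
                     list(criterion = sprintf("|dmz| <= %g ppm & |drt| <= %g min",
                                              ppmTol, rtTol))))
  mz <- rowData(pe)$mz
  rt <- rowData(pe)$rt
  # union-find over mz-sorted neighbours: duplicates are near-adjacent in mz
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  ord <- order(mz)
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in (a + 1L):n) {
      j <- ord[b]
      if (mz[j] - mz[i] > .ppmWindow(mz[j], ppmTol)) break
      if (abs(rt[i] - rt[j]) <= rtTol &&
          ppmError(mz[j], mz[i]) <= ppmTol)
        union(i, j)
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  groups <- split(seq_len(n), comp)
  if (all(lengths(groups) == 1L))
    return(.logStage(pe, "merge_duplicates", n, n,
                     list(criterion = sprintf("|dmz| <= %g ppm & |drt| <= %g min",
                                              ppmTol, rtTol), merged_groups = 0L)))
  x <- intensities(pe)
  meanInt <- rowMeans(x, na.rm = TRUE)
  keep <- integer(length(groups))
  mergeLog <- list()
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    rep <- idx[order(-meanInt[idx], mz[idx])][1L]
    keep[gi] <- rep
    if (length(idx) > 1L) {
      merged <- apply(x[idx, , drop = FALSE], 2L, function(v)
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
      x[rep, ] <- merged
      mergeLog[[length(mergeLog) + 1L]] <- list(
        kept = rowData(pe)$peak_id[rep],
        absorbed = rowData(pe)$peak_id[setdiff(idx, rep)])
    }
  }
  keep <- sort(keep)
  out <- PeakExperiment(x[keep, , drop = FALSE],
                        as.data.frame(rowData(pe))[keep, , drop = FALSE],
                        as.data.frame(colData(pe)))
  metadata(out) <- metadata(pe)
  .logStage(out, "merge_duplicates", n, length(keep),
            list(criterion = sprintf("|dmz| <= %g ppm & |drt| <= %g min",
                                     ppmTol, rtTol),
                 merged_groups = length(mergeLog), merges = mergeLog))
}
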