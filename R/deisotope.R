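# Peak nomenclature and isotope-envelope de-isotoping.
#
# Peaks are named like CP434.2167_4.58: "CP"/"CN" for the C18 column in
# positive/negative ESI, then measured m/z (4 dp) and retention time in
# minutes (2 dp). De-isotoping finds [M], [M+1], [M+2] envelopes spaced
# 1.00336 Da apart and retains only the monoisotopic member.

#' Format a peak identifier
#'
#' @param ionMode `"positive"` (prefix `CP`) or `"negative"` (`CN`).
#' @param mz Measured m/z (Da), formatted to 4 decimal places.
#' @param rt Retention time in minutes, formatted to 2 decimal places.
#' @return Character vector of peak ids, e.g. `"CP434.2167_4.58"`.
#' @examples
#' formatPeakId("positive", 434.2167, 4.58)
#' @export
formatPeakId <- function(ionMode, mz, rt) {
  stopifnot(all(mz > 0), all(rt >= 0))
  ionMode <- match.arg(ionMode, c("positive", "negative"), several.ok = TRUE)
  prefix <- ifelse(ionMode == "positive", "CP", "CN")
  sprintf("%s%.4f_%.2f", prefix, mz, rt)
}

#' Parse a peak identifier
#'
#' Inverse of [formatPeakId()].
#'
#' @param id Character vector of peak ids.
#' @return `data.frame` with columns `ion_mode`, `mz`, `rt`.
#' @examples
#' parsePeakId("CN353.0875_5.39")
#' @export
parsePeakId <- function(id) {
  m <- regmatches(id, regexec("^(CP|CN)([0-9]+\\.[0-9]{4})_([0-9]+\\.[0-9]{2})$", id))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed peak id: ", paste(id[bad], collapse = ", "))
  data.frame(
    ion_mode = ifelse(vapply(m, `[`, "", 2L) == "CP", "positive", "negative"),
    mz = as.numeric(vapply(m, `[`, "", 3L)),
    rt = as.numeric(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

# Pearson correlation over shared non-missing samples; NA if < minShared.
.pairCor <- function(x, y, minShared = 3L) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < minShared) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' Find isotope envelopes ([M], [M+1], [M+2]) in a peak table
#'
#' A candidate partner sits 1.00336 Da above its precursor within a ppm
#' window and elutes at approximately the same retention time. The whole
#' group must additionally be highly correlated across samples and show
#' mean intensity ratios `[M]/[M+1] > ratioMin` and `[M+1]/[M+2] >
#' ratioMin`. All four criteria are enforced conjointly. Groups are
#' disjoint: envelopes are assembled greedily in descending monoisotopic
#' mean intensity (ties broken by ascending m/z), and each peak joins at
#' most one group. When several peaks qualify as the same partner, the one
#' closest to the expected isotope spacing is taken (ties again by
#' ascending m/z).
#'
#' @param pe A [PeakExperiment].
#' @param ppmTol m/z window in ppm (default 20).
#' @param rtTol Apex retention-time window in minutes (default 0.2).
#' @param rMin Minimum Pearson correlation across samples (default 0.9).
#' @param ratioMin Minimum mean intensity ratio between successive envelope
#'   members (default 2).
#' @return `data.frame` with one row per group: `monoisotopic`, `plus_one`,
#'   `plus_two` (NA if absent), `r_m1`, `r_m2`, `ratio_m_m1`, `ratio_m1_m2`.
#' @export
findIsotopeGroups <- function(pe, ppmTol = 20, rtTol = 0.2,
                              rMin = 0.9, ratioMin = 2) {
  x <- intensities(pe)
  mz <- rowData(pe)$mz
  rt <- rowData(pe)$rt
  ids <- rowData(pe)$peak_id
  n <- length(ids)
  if (n < 2L)
    return(.emptyIsotopeGroups())
  meanInt <- rowMeans(x, na.rm = TRUE)

  # greedy order: strongest candidate monoisotopic ion first
  ord <- order(-meanInt, mz)
  used <- logical(n)
  out <- list()

  findPartner <- function(i, exclude) {
    target <- mz[i] + .ISOTOPE_SPACING
    tol <- .ppmWindow(target, ppmTol)
    cand <- which(!used & !exclude &
                    abs(mz - target) <= tol &
                    abs(rt - rt[i]) <= rtTol)
    cand <- setdiff(cand, i)
    if (!length(cand)) return(NA_integer_)
    cand[order(abs(mz[cand] - target), mz[cand])][1L]
  }

  for (i in ord) {
    if (used[i]) next
    excl <- logical(n)
    j <- findPartner(i, excl)
    if (is.na(j)) next
    r1 <- .pairCor(x[i, ], x[j, ])
    if (is.na(r1) || r1 <= rMin) next
    ratio1 <- meanInt[i] / meanInt[j]
    if (!is.finite(ratio1) || ratio1 <= ratioMin) next
    # optional [M+2]: must itself satisfy all criteria or is left out
    k <- findPartner(j, excl)
    r2 <- NA_real_; ratio2 <- NA_real_
    if (!is.na(k)) {
      r2 <- .pairCor(x[i, ], x[k, ])
      ratio2 <- meanInt[j] / meanInt[k]
      if (is.na(r2) || r2 <= rMin || !is.finite(ratio2) || ratio2 <= ratioMin) {
        k <- NA_integer_; r2 <- NA_real_; ratio2 <- NA_real_
      }
    }
    used[c(i, j)] <- TRUE
    if (!is.na(k)) used[k] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      monoisotopic = ids[i], plus_one = ids[j],
      plus_two = if (is.na(k)) NA_character_ else ids[k],
      r_m1 = r1, r_m2 = r2, ratio_m_m1 = ratio1, ratio_m1_m2 = ratio2,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.emptyIsotopeGroups())
  do.call(rbind, out)
}

.emptyIsotopeGroups <- function() {
  data.frame(monoisotopic = character(0), plus_one = character(0),
             plus_two = character(0), r_m1 = numeric(0), r_m2 = numeric(0),
             ratio_m_m1 = numeric(0), ratio_m1_m2 = numeric(0),
             stringsAsFactors = FALSE)
}

#' Remove isotopologue rows, keeping only monoisotopic ions
#'
#' Drops every `[M+1]` / `[M+2]` row of the supplied isotope groups and
#' records the removed partners in the surviving row's `isotope_links`
#' annotation column.
#'
#' @param pe A [PeakExperiment].
#' @param groups Isotope groups from [findIsotopeGroups()] on the same
#'   object.
#' @return The de-isotoped `PeakExperiment`.
#' @export
deisotope <- function(pe, groups) {
  if (nrow(groups) == 0L)
    return(.logStage(pe, "deisotope", nrow(pe), nrow(pe),
                     list(criterion = "isotope envelope removal", groups = 0L)))
  drop <- stats::na.omit(c(groups$plus_one, groups$plus_two))
  keep <- !(rowData(pe)$peak_id %in% drop)
  out <- pe[keep, ]
  rd <- rowData(out)
  if (!"isotope_links" %in% colnames(rd)) rd$isotope_links <- ""
  idx <- match(groups$monoisotopic, rd$peak_id)
  links <- ifelse(is.na(groups$plus_two), groups$plus_one,
                  paste(groups$plus_one, groups$plus_two, sep = ","))
  rd$isotope_links[idx[!is.na(idx)]] <- links[!is.na(idx)]
  rowData(out) <- rd
  .logStage(out, "deisotope", nrow(pe), nrow(out),
            list(criterion = "isotope envelope removal",
                 groups = nrow(groups)))
}
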