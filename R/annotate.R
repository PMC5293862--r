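# Rule-based annotation of flavonoid glycosides and alkaloids.
#
# Three lines of evidence support an annotation: (1) the isotopic partner
# of the target peak must be present at the right mass spacing and
# retention time; (2) co-eluting, highly correlated peaks are treated as
# fragment ions of the same compound; (3) the parent-minus-fragment
# neutral losses are decomposed into sugar/acyl moieties attached to a
# recognised aglycone core. Names render as aglycone symbol plus moiety
# symbols ordered from the aglycone outward, e.g. "K-Glc-maGlc".

#' Check isotopic-partner presence for a peak
#'
#' Passes when a peak at `mz + 1.00336` (within `ppmTol`) exists whose
#' apex retention time lies within the target peak's `[rtmin, rtmax]`.
#'
#' @param pe A [PeakExperiment].
#' @param peakId Target peak id.
#' @param ppmTol Mass window in ppm (default 20).
#' @return List with `passed`, `partner` (peak id or `NA`) and `detail`.
#' @export
checkIsotopicPresence <- function(pe, peakId, ppmTol = 20) {
  rd <- rowData(pe)
  i <- match(peakId, rd$peak_id)
  if (is.na(i)) stop("unknown peak: ", peakId)
  target <- rd$mz[i] + .ISOTOPE_SPACING
  cand <- which(.withinPpm(rd$mz, target, ppmTol) &
                  rd$rt >= rd$rtmin[i] & rd$rt <= rd$rtmax[i])
  cand <- setdiff(cand, i)
  if (!length(cand))
    return(list(passed = FALSE, partner = NA_character_,
                detail = "no isotopic partner within tolerance"))
  best <- cand[which.min(abs(rd$mz[cand] - target))]
  list(passed = TRUE, partner = rd$peak_id[best],
       detail = sprintf("partner %s at %.1f ppm from expected spacing",
                        rd$peak_id[best],
                        ppmError(rd$mz[best], target)))
}

#' Co-eluting correlated peak group
#'
#' Returns the peaks whose apex RT lies within `rtTol` of the seed peak
#' and whose intensity profile across samples has Pearson correlation
#' above `rMin` with the seed, sorted by descending m/z (the seed is
#' always included). Candidates sharing fewer than 3 non-missing samples
#' with the seed are skipped with a notice.
#'
#' @param pe A [PeakExperiment].
#' @param seedPeak Seed peak id.
#' @param rMin Minimum Pearson correlation (default 0.9).
#' @param rtTol Co-elution window in minutes (default 0.05).
#' @return Character vector of peak ids, descending m/z.
#' @export
coelutingGroup <- function(pe, seedPeak, rMin = 0.9, rtTol = 0.05) {
  rd <- rowData(pe)
  i <- match(seedPeak, rd$peak_id)
  if (is.na(i)) stop("unknown peak: ", seedPeak)
  x <- intensities(pe)
  cand <- which(abs(rd$rt - rd$rt[i]) <= rtTol)
  keep <- logical(length(cand))
  skipped <- 0L
  for (ci in seq_along(cand)) {
    j <- cand[ci]
    if (j == i) { keep[ci] <- TRUE; next }
    shared <- sum(!is.na(x[i, ]) & !is.na(x[j, ]))
    if (shared < 3L) { skipped <- skipped + 1L; next }
    r <- .pairCor(x[i, ], x[j, ])
    keep[ci] <- !is.na(r) && r > rMin
  }
  if (skipped)
    message(skipped, " co-eluting peaks skipped (< 3 shared samples)")
  sel <- cand[keep]
  rd$peak_id[sel[order(-rd$mz[sel])]]
}

#' Annotate a glycoside from its parent and fragment ions
#'
#' Greedy neutral-loss decomposition. One observed ion (a fragment or the
#' parent itself) must match an aglycone adduct m/z within `ppmTol`; the
#' mass between the parent and the aglycone ion is then explained as an
#' ordered sum of moiety losses. Losses directly evidenced by differences
#' between successive observed ions are preferred; any remaining gap is
#' closed by the smallest moiety multiset (ties broken lexicographically
#' by symbol). The reconstructed parent m/z (aglycone + losses + adduct)
#' must agree with the observed parent within `ppmTol`. Isobaric aglycones
#' (kaempferol/luteolin) are reported as an ambiguous set, never resolved.
#' Failure to annotate returns an unannotated result with the partial
#' evidence collected, not an error.
#'
#' @param parentMz Observed parent ion m/z (Da).
#' @param fragmentMzs Numeric vector of co-eluting fragment ion m/z values
#'   (may be empty).
#' @param adduct `"[M+H]+"` or `"[M-H]-"`.
#' @param aglycones Aglycone library (default [aglyconeLibrary()] for the
#'   adduct's ion mode).
#' @param moieties Moiety library (default [moietyLibrary()]).
#' @param ppmTol Mass tolerance in ppm (default 20).
#' @param maxMoieties Largest moiety multiset searched (default 4).
#' @return List of class `glycosideAnnotation`: `name` (e.g.
#'   `"K-Glc-maGlc"`, or `NA` when unannotated), `aglycone`,
#'   `ambiguousAglycones`, `moieties` (ordered from the aglycone outward),
#'   `residualPpm`, and `evidence` (data.frame of criterion/passed/detail).
#' @export
annotateGlycoside <- function(parentMz, fragmentMzs = numeric(0),
                              adduct = c("[M+H]+", "[M-H]-"),
                              aglycones = NULL, moieties = moietyLibrary(),
                              ppmTol = 20, maxMoieties = 4) {
  adduct <- match.arg(adduct)
  ionMode <- if (adduct == "[M+H]+") "positive" else "negative"
  if (is.null(aglycones)) aglycones <- aglyconeLibrary(ionMode)
  stopifnot(parentMz > 0)
  ions <- sort(unique(c(parentMz, fragmentMzs)), decreasing = TRUE)
  tolDa <- .ppmWindow(parentMz, ppmTol)
  evidence <- list()
  addEv <- function(criterion, passed, detail)
    evidence[[length(evidence) + 1L]] <<- data.frame(
      criterion = criterion, passed = passed, detail = detail,
      stringsAsFactors = FALSE)

  # 1. aglycone ion: lowest-m/z observed ion matching a library adduct m/z
  aglMatch <- NULL
  for (ion in rev(ions)) {  # ascending: prefer the smallest matching ion
    hits <- which(!is.na(aglycones$adductMz) &
                    .withinPpm(ion, aglycones$adductMz, ppmTol))
    if (length(hits)) { aglMatch <- list(ion = ion, rows = hits); break }
  }
  if (is.null(aglMatch)) {
    # no observed aglycone ion: hypothesise each library aglycone and keep
    # the one whose residual decomposes with the fewest moieties (ties by
    # library order); isobaric aglycones share the solution and stay
    # ambiguous
    hyp <- NULL
    for (i in seq_len(nrow(aglycones))) {
      amz <- aglycones$adductMz[i]
      if (is.na(amz) || parentMz < amz - tolDa) next
      losses <- if (abs(parentMz - amz) <= tolDa) character(0)
                else .moietyMultiset(parentMz - amz, moieties, tolDa,
                                     maxMoieties)
      if (is.null(losses)) next
      if (is.null(hyp) || length(losses) < length(hyp$losses))
        hyp <- list(row = i, losses = losses, adductMz = amz)
    }
    if (is.null(hyp)) {
      addEv("aglycone_match", FALSE,
            "no observed ion matches a known aglycone and no hypothesis decomposes")
      return(.unannotated(parentMz, evidence))
    }
    rows <- which(!is.na(aglycones$adductMz) &
                    abs(aglycones$adductMz - hyp$adductMz) < 1e-6)
    agl <- aglycones[rows[1L], ]
    ambiguous <- aglycones$name[rows]
    addEv("aglycone_match", TRUE,
          sprintf("aglycone %s inferred by mass only (no supporting fragment)%s",
                  agl$name,
                  if (length(rows) > 1L)
                    paste0("; ambiguous with ",
                           paste(aglycones$name[rows[-1L]], collapse = ", "))
                  else ""))
    losses <- hyp$losses
    if (length(losses))
      addEv("moiety_decomposition", TRUE,
            paste("moieties by mass only:", paste(losses, collapse = ", ")))
    return(.finishAnnotation(parentMz, agl, ambiguous, losses, moieties,
                             ppmTol, evidence, addEv, lossOrder = FALSE))
  }
  rows <- aglMatch$rows
  agl <- aglycones[rows[1L], ]  # library order fixes the displayed symbol
  ambiguous <- aglycones$name[rows]
  addEv("aglycone_match", TRUE,
        sprintf("ion %.4f matches %s (%.1f ppm)%s", aglMatch$ion,
                agl$name, ppmError(aglMatch$ion, agl$adductMz),
                if (length(rows) > 1L)
                  paste0("; ambiguous with ",
                         paste(aglycones$name[rows[-1L]], collapse = ", "))
                else ""))

  # 2. evidence-first chain: walk parent -> ... -> aglycone ion through
  #    observed ions, matching each step to a single moiety loss
  chainIons <- ions[ions >= aglMatch$ion - tolDa & ions <= parentMz + tolDa]
  losses <- character(0)
  chainOk <- TRUE
  cur <- parentMz
  while (cur - aglMatch$ion > tolDa) {
    nxt <- chainIons[chainIons < cur - tolDa]
    stepFound <- FALSE
    for (ni in nxt) {  # descending: largest next ion = smallest loss first
      gap <- cur - ni
      hit <- which(abs(moieties$lossMass - gap) <= tolDa)
      if (length(hit)) {
        losses <- c(losses, moieties$symbol[hit[1L]])
        cur <- ni
        stepFound <- TRUE
        break
      }
    }
    if (!stepFound) { chainOk <- FALSE; break }
  }
  lossOrder <- TRUE
  if (chainOk && length(losses)) {
    addEv("fragment_chain", TRUE,
          paste("observed losses:", paste(losses, collapse = ", ")))
  } else if (!chainOk) {
    addEv("fragment_chain", FALSE,
          "observed ions do not chain by single moiety losses")
  }

  # 3. fall back to multiset search on the parent - aglycone residual
  if (!chainOk) {
    residual <- parentMz - agl$adductMz
    losses <- .moietyMultiset(residual, moieties, tolDa, maxMoieties)
    lossOrder <- FALSE
    if (is.null(losses)) {
      addEv("moiety_decomposition", FALSE,
            sprintf("residual %.4f Da not decomposable into <= %d moieties",
                    residual, maxMoieties))
      return(.unannotated(parentMz, evidence,
                          aglycone = agl$name, ambiguous = ambiguous))
    }
    addEv("moiety_decomposition", TRUE,
          paste("moieties by mass only:", paste(losses, collapse = ", ")))
  }

  .finishAnnotation(parentMz, agl, ambiguous, losses, moieties, ppmTol,
                    evidence, addEv, lossOrder = lossOrder)
}

# shared annotation tail: soundness check, sugar-identity note, rendering.
# `lossOrder = TRUE` marks losses recorded from the parent inward (the
# rendered name reverses them into attachment order); canonical multiset
# solutions are used as-is.
.finishAnnotation <- function(parentMz, agl, ambiguous, losses, moieties,
                              ppmTol, evidence, addEv, lossOrder) {
  recomposed <- agl$adductMz +
    sum(moieties$lossMass[match(losses, moieties$symbol)])
  resPpm <- ppmError(parentMz, recomposed)
  addEv("parent_recomposition", resPpm <= ppmTol,
        sprintf("recomposed %.4f vs observed %.4f (%.1f ppm)",
                recomposed, parentMz, resPpm))
  evidence <- environment(addEv)$evidence
  if (resPpm > ppmTol)
    return(.unannotated(parentMz, evidence,
                        aglycone = agl$name, ambiguous = ambiguous))
  if (any(losses %in% c("Glc", "Rha"))) {
    addEv("sugar_identity_assumption", TRUE,
          "hexose reported as Glc, deoxyhexose as Rha (accurate mass cannot distinguish stereoisomers)")
    evidence <- environment(addEv)$evidence
  }
  ordered <- if (lossOrder) rev(losses) else losses
  structure(list(
    name = paste(c(agl$symbol, ordered), collapse = "-"),
    aglycone = agl$name,
    ambiguousAglycones = ambiguous,
    moieties = moieties$name[match(ordered, moieties$symbol)],
    moietySymbols = ordered,
    parentMz = parentMz,
    residualPpm = resPpm,
    evidence = do.call(rbind, evidence)
  ), class = "glycosideAnnotation")
}

.unannotated <- function(parentMz, evidence, aglycone = NA_character_,
                         ambiguous = character(0)) {
  structure(list(
    name = NA_character_, aglycone = aglycone,
    ambiguousAglycones = ambiguous, moieties = character(0),
    moietySymbols = character(0), parentMz = parentMz,
    residualPpm = NA_real_,
    evidence = if (length(evidence)) do.call(rbind, evidence) else
      data.frame(criterion = character(0), passed = logical(0),
                 detail = character(0))
  ), class = "glycosideAnnotation")
}

#' @export
print.glycosideAnnotation <- function(x, ...) {
  if (is.na(x$name)) {
    cat("unannotated peak (parent m/z", sprintf("%.4f", x$parentMz), ")\n")
  } else {
    cat(x$name, " (parent m/z ", sprintf("%.4f", x$parentMz),
        ", residual ", sprintf("%.1f", x$residualPpm), " ppm)\n", sep = "")
    if (length(x$ambiguousAglycones) > 1L)
      cat("  aglycone ambiguous:",
          paste(x$ambiguousAglycones, collapse = " / "), "\n")
  }
  invisible(x)
}

# Smallest moiety multiset (<= maxN members) whose loss masses sum to
# `residual` within tolDa; ties broken lexicographically by symbol
# sequence. NULL when no multiset fits.
.moietyMultiset <- function(residual, moieties, tolDa, maxN) {
  syms <- moieties$symbol[order(moieties$symbol)]
  mass <- moieties$lossMass[order(moieties$symbol)]
  for (n in seq_len(maxN)) {
    combos <- .multisets(length(syms), n)
    for (ci in seq_len(nrow(combos))) {
      idx <- combos[ci, ]
      if (abs(sum(mass[idx]) - residual) <= tolDa)
        return(syms[idx])
    }
  }
  NULL
}

# all non-decreasing index tuples of length n from 1..k (multisets),
# enumerated in lexicographic order
.multisets <- function(k, n) {
  if (n == 1L) return(matrix(seq_len(k), ncol = 1L))
  sub <- .multisets(k, n - 1L)
  out <- list()
  for (i in seq_len(k)) {
    rows <- sub[sub[, 1L] >= i, , drop = FALSE]
    out[[i]] <- cbind(i, rows)
  }
  do.call(rbind, out)
}
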