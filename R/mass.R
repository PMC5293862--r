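# Accurate-mass arithmetic: molecular formulas, adduct m/z, ppm errors.

# CODATA monoisotopic atomic masses (Da). 12C defines the scale exactly.
.ELEMENT_MASSES <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163
)

# mass of a proton (not the hydrogen atom): used for [M+H]+ / [M-H]-
.PROTON_MASS <- 1.007276466

# 13C - 12C spacing between successive isotopologue peaks
.ISOTOPE_SPACING <- 1.00336

# natural abundance of 13C, used for the binomial isotope-envelope model
.P13C <- 0.0107

#' Parse a molecular formula
#'
#' Parses an elemental formula string such as `"C15H10O6"` into a named
#' integer vector of element counts. Elements C, H, N, O, S and P are
#' supported, which covers the flavonoid and alkaloid chemistry this
#' package annotates.
#'
#' @param text Formula string, e.g. `"C23H31NO7"`.
#' @return Named integer vector of element counts.
#' @examples
#' parseFormula("C15H10O6")
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text))
    stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(text))
    stop("malformed formula: ", text)
  counts <- integer(0)
  for (tok in tokens) {
    el <- sub("[0-9]+$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.ELEMENT_MASSES))
      stop("unknown element symbol '", el, "' in formula ", text)
    counts[el] <- if (el %in% names(counts)) counts[[el]] + n else n
  }
  if (all(counts == 0L))
    stop("formula has no atoms: ", text)
  counts
}

#' Monoisotopic mass of a formula
#'
#' @param formula Either a formula string or a named count vector as
#'   returned by [parseFormula()].
#' @return Monoisotopic neutral mass in Da.
#' @examples
#' monoisotopicMass("C15H10O6")  # kaempferol / luteolin, 286.0477
#' @export
monoisotopicMass <- function(formula) {
  if (is.character(formula)) formula <- parseFormula(formula)
  sum(.ELEMENT_MASSES[names(formula)] * formula)
}

#' Ion m/z for an adduct of a neutral mass
#'
#' Supports the two electrospray adducts the pipeline works with:
#' protonation `[M+H]+` and deprotonation `[M-H]-`. The proton mass
#' (1.007276 Da) is used, not the hydrogen atom mass.
#'
#' @param neutralMass Neutral monoisotopic mass in Da.
#' @param adduct `"[M+H]+"` or `"[M-H]-"`.
#' @return Ion m/z in Da (full precision; round to 4 decimals for display).
#' @examples
#' adductMz(monoisotopicMass("C15H10O6"), "[M+H]+")  # 287.0550
#' @export
adductMz <- function(neutralMass, adduct = c("[M+H]+", "[M-H]-")) {
  stopifnot(is.numeric(neutralMass), all(neutralMass > 0))
  adduct <- match.arg(adduct)
  if (adduct == "[M+H]+") neutralMass + .PROTON_MASS
  else neutralMass - .PROTON_MASS
}

#' Adduct for an ion mode
#'
#' @param ionMode `"positive"` or `"negative"`.
#' @return The corresponding ESI adduct label.
#' @export
ionModeAdduct <- function(ionMode = c("positive", "negative")) {
  ionMode <- match.arg(ionMode)
  if (ionMode == "positive") "[M+H]+" else "[M-H]-"
}

#' Relative mass error in parts per million
#'
#' @param observed Observed m/z (Da).
#' @param theoretical Theoretical m/z (Da); must be positive.
#' @return Nonnegative ppm error, `|observed - theoretical| / theoretical * 1e6`.
#' @examples
#' ppmError(333.1174, 333.1234)  # ~18 ppm
#' @export
ppmError <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  abs(observed - theoretical) / theoretical * 1e6
}

# absolute Da tolerance corresponding to a ppm window around mz
.ppmWindow <- function(mz, ppm) mz * ppm / 1e6

# TRUE where observed lies within ppm of theoretical
.withinPpm <- function(observed, theoretical, ppm) {
  ppmError(observed, theoretical) <= ppm
}
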