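# Built-in compound knowledge used by the annotation rules: flavonoid /
# alkaloid aglycone cores and the neutral-loss masses of sugar/acyl moieties.

#' Aglycone library
#'
#' The aglycone cores recognised by the glycoside annotator. The symbols are
#' the conventional one/three-letter shorthands used when rendering names
#' such as `"K-Glc-maGlc"`. Kaempferol and luteolin are isobaric
#' (both C15H10O6); when a matched ion is consistent with both, the
#' annotation reports the ambiguity rather than resolving it.
#'
#' Perloline has no formula entry: only its reference calculated m/z
#' (333.1234, `[M+H]+`) is stored, and matching uses that value directly.
#' For chlorogenic acid the formula-derived `[M-H]-` m/z (353.0878)
#' disagrees with the commonly quoted calculated value 353.0867 by about
#' 3 ppm; both are stored and the `referenceDiscrepancyPpm` column reports
#' the difference instead of silently preferring either.
#'
#' @param ionMode `"positive"` or `"negative"`; sets which adduct m/z the
#'   `adductMz` column carries.
#' @return `data.frame` with columns `name`, `symbol`, `formula`,
#'   `neutralMass`, `adductMz`, `referenceMz`, `referenceDiscrepancyPpm`.
#' @examples
#' aglyconeLibrary()[, c("name", "symbol", "adductMz")]
#' @export
aglyconeLibrary <- function(ionMode = c("positive", "negative")) {
  ionMode <- match.arg(ionMode)
  lib <- data.frame(
    name = c("kaempferol", "luteolin", "quercetin", "isorhamnetin",
             "thesinine", "chlorogenic acid", "perloline"),
    symbol = c("K", "Lut", "Q", "I", "The", "CGA", "Per"),
    formula = c("C15H10O6", "C15H10O6", "C15H10O7", "C16H12O7",
                "C17H21NO3", "C16H18O9", NA),
    referenceMz = c(NA, NA, NA, NA, NA,
                    if (ionMode == "negative") 353.0867 else NA,
                    if (ionMode == "positive") 333.1234 else NA),
    stringsAsFactors = FALSE
  )
  lib$neutralMass <- vapply(lib$formula, function(f)
    if (is.na(f)) NA_real_ else monoisotopicMass(f), numeric(1))
  adduct <- ionModeAdduct(ionMode)
  lib$adductMz <- lib$referenceMz
  hasF <- !is.na(lib$neutralMass)
  lib$adductMz[hasF] <- adductMz(lib$neutralMass[hasF], adduct)
  lib$referenceDiscrepancyPpm <- NA_real_
  both <- !is.na(lib$referenceMz) & !is.na(lib$neutralMass)
  lib$referenceDiscrepancyPpm[both] <-
    ppmError(lib$referenceMz[both], adductMz(lib$neutralMass[both], adduct))
  lib
}

#' Sugar and acyl moiety library
#'
#' Neutral-loss masses of the glycoside moieties recognised during
#' annotation. Following common practice for plant flavonoid O-glycosides,
#' a hexose loss is reported as glucose (Glc) and a deoxyhexose loss as
#' rhamnose (Rha); the choice is an assumption recorded in the annotation
#' evidence, since accurate mass cannot distinguish stereoisomeric sugars.
#'
#' @return `data.frame` with columns `name`, `symbol`, `formula`, `lossMass`
#'   (monoisotopic neutral-loss mass, Da).
#' @examples
#' moietyLibrary()
#' @export
moietyLibrary <- function() {
  lib <- data.frame(
    name = c("hexose", "deoxyhexose", "acetylhexose", "malonylhexose",
             "feruloylhexose"),
    symbol = c("Glc", "Rha", "acGlc", "maGlc", "feruloylGlc"),
    formula = c("C6H10O5", "C6H10O4", "C8H12O6", "C9H12O8", "C16H18O8"),
    stringsAsFactors = FALSE
  )
  lib$lossMass <- vapply(lib$formula, monoisotopicMass, numeric(1))
  lib
}
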