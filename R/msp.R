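# NIST MSP spectral library text format.
#
# Records are blocks of "Name:", "PrecursorMZ:", "Num Peaks:" headers
# followed by one "m/z intensity" pair per line, separated by blank lines.

#' Write spectra to a NIST MSP library
#'
#' @param records List of spectra; each a list with `name` (character),
#'   `precursorMz` (numeric) and `ions` (`data.frame` with columns `mz`,
#'   `intensity`).
#' @param file Path to write, or `NULL` to return the text.
#' @return The MSP text, invisibly when written to a file.
#' @export
writeMsp <- function(records, file = NULL) {
  blocks <- vapply(records, function(rec) {
    stopifnot(!is.null(rec$name), !is.null(rec$precursorMz),
              is.data.frame(rec$ions))
    paste0(
      "Name: ", rec$name, "\n",
      "PrecursorMZ: ", sprintf("%.4f", rec$precursorMz), "\n",
      "Num Peaks: ", nrow(rec$ions), "\n",
      paste(sprintf("%.4f %g", rec$ions$mz, rec$ions$intensity),
            collapse = "\n"),
      if (nrow(rec$ions)) "\n" else ""
    )
  }, character(1))
  text <- paste(blocks, collapse = "\n")
  if (is.null(file)) return(text)
  writeLines(text, file)
  invisible(text)
}

#' Read a NIST MSP library
#'
#' @param file Path to an MSP file, or a character scalar of MSP text.
#' @return List of spectra in the shape accepted by [writeMsp()].
#' @export
readMsp <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file)
           else strsplit(paste(file, collapse = "\n"), "\n")[[1L]]
  records <- list()
  rec <- NULL
  expected <- NA_integer_
  flush <- function() {
    if (is.null(rec)) return()
    if (!is.na(expected) && nrow(rec$ions) != expected)
      stop("Num Peaks mismatch in record '", rec$name, "': declared ",
           expected, ", found ", nrow(rec$ions))
    records[[length(records) + 1L]] <<- rec
    rec <<- NULL
    expected <<- NA_integer_
  }
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) { flush(); next }
    if (grepl("^Name:", line)) {
      flush()
      rec <- list(name = trimws(sub("^Name:", "", line)),
                  precursorMz = NA_real_,
                  ions = data.frame(mz = numeric(0), intensity = numeric(0)))
    } else if (grepl("^PrecursorMZ:", line, ignore.case = TRUE)) {
      if (is.null(rec)) stop("PrecursorMZ before Name at line ", ln)
      rec$precursorMz <- as.numeric(sub("^PrecursorMZ:", "", line,
                                        ignore.case = TRUE))
    } else if (grepl("^Num Peaks:", line, ignore.case = TRUE)) {
      if (is.null(rec)) stop("Num Peaks before Name at line ", ln)
      expected <- as.integer(sub("^Num Peaks:", "", line, ignore.case = TRUE))
    } else {
      parts <- strsplit(line, "[ \t;]+")[[1L]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) < 2L || anyNA(vals[1:2]))
        stop("malformed MSP line ", ln, ": '", lines[ln], "'")
      if (is.null(rec)) stop("ion line before Name at line ", ln)
      rec$ions <- rbind(rec$ions,
                        data.frame(mz = vals[1L], intensity = vals[2L]))
    }
  }
  flush()
  records
}
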