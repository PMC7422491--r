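# Delimited-text interchange: one file per segment plus a manifest.

#' Read one segment from delimited text
#'
#' Expects UTF-8 comma-separated text with a literal header
#' `sample_index,value_uV` and dot-decimal numbers (locale decimal commas
#' are a format error). Rows must be complete and numeric; the first
#' malformed cell is reported with its line number.
#'
#' @param path file path.
#' @param samplingRate sampling rate to attach, Hz (from the dataset
#'   manifest or a flag; default 256).
#' @return numeric vector of samples (uV), with attribute `samplingRate`.
#' @export
readDelimitedSegment <- function(path, samplingRate = 256) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !identical(trimws(lines[1]),
                                   "sample_index,value_uV")) {
    stop("format error in ", path,
         ": missing header 'sample_index,value_uV'")
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("format error in ", path, " at line ", bad[1] + 1L,
         ": expected two comma-separated fields")
  }
  tab <- matrix(trimws(unlist(parts)), ncol = 2L, byrow = TRUE)
  suppressWarnings({
    idx <- as.numeric(tab[, 1])
    val <- as.numeric(tab[, 2])
  })
  badCell <- which(is.na(idx) | is.na(val))
  if (length(badCell)) {
    stop("format error in ", path, " at line ", badCell[1] + 1L,
         ": non-numeric cell (dot-decimal dialect only)")
  }
  structure(val[order(idx)], samplingRate = samplingRate)
}

.write_segment_text <- function(x, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("sample_index,value_uV", con)
  writeLines(sprintf("%d,%.10g", seq_along(x) - 1L, x), con)
  invisible(path)
}
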