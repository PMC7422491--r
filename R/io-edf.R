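# Minimal EDF (European Data Format) writer and reader: 16-bit samples,
# standard 256-byte header plus 256 bytes per signal, physical dimension
# microvolts. Covers the subset of EDF needed to interchange fixed-length
# multichannel segments; EDF+ annotations are out of scope.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)   # left-justified, space-padded
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  .edf_pad(s, width)
}

#' Write one multichannel EDF file
#'
#' Writes `signals` (a list of equal-length numeric matrices, one per
#' channel, one column per data record) as 16-bit EDF: one EDF signal per
#' channel labeled with the channel name, physical dimension `uV`, one
#' data record per matrix column. Physical calibration spans the observed
#' per-channel amplitude range, so the quantization step is
#' `(max - min) / 65535`.
#'
#' @param signals named list of numeric matrices (samplesPerRecord x
#'   nRecords), one per channel; all dimensions must agree.
#' @param path output path.
#' @param recordSeconds duration of one data record, s.
#' @param patientId,recordingId free-text EDF header fields.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(signals, path, recordSeconds = 10,
                     patientId = "X", recordingId = "eegbench") {
  stopifnot(is.list(signals), length(signals) >= 1L,
            !is.null(names(signals)))
  dims <- vapply(signals, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all channel matrices must have identical dimensions")
  }
  spr <- dims[1, 1]
  nRec <- dims[2, 1]
  ns <- length(signals)

  pmin <- vapply(signals, function(m) min(m, -1), numeric(1))
  pmax <- vapply(signals, function(m) max(m, 1), numeric(1))
  dmin <- -32768; dmax <- 32767

  con <- file(path, open = "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(.edf_pad("0", 8))
  wr(.edf_pad(patientId, 80))
  wr(.edf_pad(recordingId, 80))
  wr(.edf_pad("01.01.00", 8))
  wr(.edf_pad("00.00.00", 8))
  wr(.edf_pad(256 * (ns + 1), 8))
  wr(.edf_pad("", 44))
  wr(.edf_pad(nRec, 8))
  wr(.edf_num(recordSeconds, 8))
  wr(.edf_pad(ns, 4))
  for (nm in names(signals)) wr(.edf_pad(nm, 16))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))          # transducer
  for (i in seq_len(ns)) wr(.edf_pad("uV", 8))
  for (i in seq_len(ns)) wr(.edf_num(pmin[i], 8))
  for (i in seq_len(ns)) wr(.edf_num(pmax[i], 8))
  for (i in seq_len(ns)) wr(.edf_pad(dmin, 8))
  for (i in seq_len(ns)) wr(.edf_pad(dmax, 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))          # prefiltering
  for (i in seq_len(ns)) wr(.edf_pad(spr, 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 32))

  # physical values re-read from the truncated ASCII header fields, so the
  # writer and a conforming reader agree on calibration exactly
  pminH <- as.numeric(trimws(vapply(pmin, .edf_num, "", width = 8)))
  pmaxH <- as.numeric(trimws(vapply(pmax, .edf_num, "", width = 8)))
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      v <- signals[[i]][, r]
      dig <- round((v - pminH[i]) / (pmaxH[i] - pminH[i]) *
                     (dmax - dmin) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

.edf_read_field <- function(raw, offset, width) {
  rawToChar(raw[(offset + 1):(offset + width)])
}

#' Read an EDF file
#'
#' Parses the header and all data records of a 16-bit EDF file, returning
#' one physically calibrated signal matrix per channel. Malformed headers
#' are reported with the byte offset of the offending field; a file whose
#' length disagrees with its header (truncation) is rejected outright --
#' no partial data is returned. Unknown channel labels are passed through
#' verbatim.
#'
#' @param path EDF file path.
#' @return list with `signals` (named list of samplesPerRecord x nRecords
#'   matrices, in uV for uV-dimensioned signals), `samplingRate` (per
#'   channel, Hz), `recordSeconds` and `nRecords`.
#' @export
readEDF <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.info(path)$size
  if (sz < 256) stop("format error at byte 0: file shorter than an ",
                     "EDF header (", sz, " bytes)")
  con <- file(path, open = "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256)
  ver <- trimws(.edf_read_field(hdr, 0, 8))
  if (!identical(ver, "0")) {
    stop("format error at byte 0: unsupported EDF version '", ver, "'")
  }
  hdrBytes <- suppressWarnings(
    as.integer(trimws(.edf_read_field(hdr, 184, 8))))
  nRec <- suppressWarnings(as.integer(trimws(.edf_read_field(hdr, 236, 8))))
  recSec <- suppressWarnings(
    as.numeric(trimws(.edf_read_field(hdr, 244, 8))))
  ns <- suppressWarnings(as.integer(trimws(.edf_read_field(hdr, 252, 4))))
  if (is.na(ns) || ns < 1) stop("format error at byte 252: signal count")
  if (is.na(nRec) || nRec < 0) {
    stop("format error at byte 236: record count")
  }
  if (is.na(hdrBytes) || hdrBytes != 256 * (ns + 1)) {
    stop("format error at byte 184: header size field")
  }
  if (sz < hdrBytes) {
    stop("format error: truncated header (", sz, " of ", hdrBytes,
         " bytes)")
  }
  sig <- readBin(con, "raw", hdrBytes - 256)
  # cumulative byte offsets of the per-signal header arrays
  labels <- trimws(vapply(seq_len(ns) - 1L, function(i) {
    .edf_read_field(sig, i * 16, 16)
  }, ""))
  base <- ns * 16 + ns * 80   # skip transducer block
  dim8 <- function(k) {
    vapply(seq_len(ns) - 1L, function(i) {
      .edf_read_field(sig, base + k * ns * 8 + i * 8, 8)
    }, "")
  }
  physDim <- trimws(dim8(0))
  pmin <- suppressWarnings(as.numeric(trimws(dim8(1))))
  pmax <- suppressWarnings(as.numeric(trimws(dim8(2))))
  dmin <- suppressWarnings(as.numeric(trimws(dim8(3))))
  dmax <- suppressWarnings(as.numeric(trimws(dim8(4))))
  sprOff <- base + 5 * ns * 8 + ns * 80
  spr <- suppressWarnings(as.integer(trimws(vapply(seq_len(ns) - 1L,
    function(i) .edf_read_field(sig, sprOff + i * 8, 8), ""))))
  if (anyNA(c(pmin, pmax, dmin, dmax)) || anyNA(spr)) {
    stop("format error at byte ", 256 + base,
         ": non-numeric calibration field")
  }
  expect <- hdrBytes + nRec * sum(spr) * 2
  if (sz != expect) {
    stop("format error: file has ", sz, " bytes but the header implies ",
         expect, " (truncated or trailing garbage); no data returned")
  }
  out <- lapply(seq_len(ns), function(i) {
    matrix(NA_real_, nrow = spr[i], ncol = nRec)
  })
  names(out) <- labels
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L,
                     endian = "little", signed = TRUE)
      out[[i]][, r] <- (dig - dmin[i]) / (dmax[i] - dmin[i]) *
        (pmax[i] - pmin[i]) + pmin[i]
    }
  }
  list(signals = out, samplingRate = spr / recSec,
       recordSeconds = recSec, nRecords = nRec, physDim = physDim)
}
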