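# Daubechies-8 filter bank and the subband decomposition of EEG segments.

# Orthonormal Daubechies scaling filter with 8 vanishing moments (16 taps).
# These are the standard published constants; the analysis/synthesis
# filters below are derived from them by the usual quadrature-mirror
# relations.
.db8_rec_lo <- c(
   5.441584224308161e-02,  3.128715909144659e-01,  6.756307362980128e-01,
   5.853546836548691e-01, -1.582910525602155e-02, -2.840155429624281e-01,
   4.724845739132827e-04,  1.287474266204893e-01, -1.736930100202211e-02,
  -4.408825393106472e-02,  1.398102791739828e-02,  8.746094047015655e-03,
  -4.870352993451574e-03, -3.917403729959771e-04,  6.754494059985568e-04,
  -1.174767841247695e-04
)

.wavelet_filters <- function(wavelet = "db8") {
  if (!identical(wavelet, "db8")) {
    stop("unsupported wavelet '", wavelet, "': only 'db8' is implemented")
  }
  rec_lo <- .db8_rec_lo
  F <- length(rec_lo)
  rec_hi <- rev(rec_lo) * (-1)^(seq_len(F) - 1)   # QMF
  list(
    dec_lo = rev(rec_lo),
    dec_hi = rev(rec_hi),
    rec_lo = rec_lo,
    rec_hi = rec_hi
  )
}

# Subband table for a 6-level decomposition. The nominal Hz ranges are the
# conventional brain-wave display labels attached to D1..A6 in the
# benchmark protocol; the dyadic columns give the ranges the transform
# actually realizes at the given sampling rate (fs/2^(l+1) .. fs/2^l),
# i.e. 128/64/32/16/8/4 Hz edges at 256 Hz. The labels are kept as
# metadata, not "corrected".
.subband_table <- function(levels = 6L, samplingRate = 256) {
  codes <- c(paste0("D", seq_len(levels)), paste0("A", levels))
  dyadicHigh <- c(samplingRate / 2^seq_len(levels),
                  samplingRate / 2^(levels + 1))
  dyadicLow <- c(samplingRate / 2^(seq_len(levels) + 1), 0)
  tab <- data.frame(code = codes, wave = NA_character_,
                    nominalLowHz = NA_real_, nominalHighHz = NA_real_,
                    dyadicLowHz = dyadicLow, dyadicHighHz = dyadicHigh,
                    stringsAsFactors = FALSE)
  if (levels == 6L) {
    tab$wave <- c("noise", "noise", "gamma", "beta", "alpha", "theta",
                  "delta")
    tab$nominalLowHz <- c(125, 63, 30, 13, 8, 4, 0)
    tab$nominalHighHz <- c(256, 125, 63, 30, 13, 7, 4)
  }
  tab
}

# Canonical order in which the five retained brain waves are reported,
# from fastest to slowest.
.brainwave_order <- c("gamma", "beta", "alpha", "theta", "delta")

#' Decompose an EEG segment into wavelet subbands
#'
#' Runs a multilevel discrete wavelet transform (Daubechies-8, six levels by
#' default) on one segment and returns the time-domain reconstruction of
#' every subband: each detail level and the final approximation are inverted
#' with all other coefficients zeroed, yielding seven band-limited signals
#' of the input length whose sum equals the input to floating-point
#' accuracy. At 256 Hz the subbands are D1 (noise, 125-256 Hz), D2 (noise,
#' 63-125 Hz), D3 (gamma, 30-63 Hz), D4 (beta, 13-30 Hz), D5 (alpha,
#' 8-13 Hz), D6 (theta, 4-7 Hz) and A6 (delta, 0-4 Hz).
#'
#' Signal boundaries are handled by symmetric (half-sample) extension, which
#' minimises edge artifacts while preserving perfect reconstruction; the
#' mode is recorded in the result.
#'
#' @param x numeric vector, the segment samples (uV).
#' @param samplingRate sampling rate in Hz (default 256).
#' @param wavelet wavelet name; only `"db8"` is implemented.
#' @param levels decomposition depth (default 6).
#' @param boundary boundary mode; only `"symmetric"` is implemented.
#' @return a [SubbandSet-class].
#' @examples
#' x <- sin(2 * pi * 40 * seq(0, 10, length.out = 2560))
#' sb <- decomposeSegment(x)
#' colnames(bandSignals(sb))
#' @export
decomposeSegment <- function(x, samplingRate = 256, wavelet = "db8",
                             levels = 6L, boundary = "symmetric") {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("segment contains non-finite samples")
  levels <- as.integer(levels)
  if (length(x) < 2^levels) {
    stop("segment of length ", length(x), " is too short for a ", levels,
         "-level decomposition (need >= ", 2^levels, ")")
  }
  if (!identical(boundary, "symmetric")) {
    stop("unsupported boundary mode '", boundary, "'")
  }
  flt <- .wavelet_filters(wavelet)
  rec <- .band_recon_c(x, flt$dec_lo, flt$dec_hi, flt$rec_lo, flt$rec_hi,
                       levels)
  info <- .subband_table(levels, samplingRate)
  colnames(rec) <- info$code
  new("SubbandSet", bands = rec, bandInfo = info,
      samplingRate = samplingRate, wavelet = wavelet, boundary = boundary)
}

#' Subband signal matrix of a decomposition
#'
#' @name bandSignals
#' @param x a [SubbandSet-class].
#' @param ... unused.
#' @return numeric matrix, one column per subband (`D1` ... `A6`), one row
#'   per sample point of the decomposed segment.
#' @export
setMethod("bandSignals", "SubbandSet", function(x, ...) x@bands)

#' @rdname design-accessors
#' @export
setMethod("samplingRate", "SubbandSet", function(x) x@samplingRate)

#' Keep the five named brain waves, discard the noise bands
#'
#' Drops the two finest detail bands (D1, D2 -- nominally 63-256 Hz, treated
#' as noise) from a full subband decomposition and returns the remaining
#' five reconstructions named by their brain wave, ordered gamma, beta,
#' alpha, theta, delta.
#'
#' @name retainBrainwaves
#' @param x a [SubbandSet-class] from [decomposeSegment()].
#' @return numeric matrix with columns `gamma`, `beta`, `alpha`, `theta`,
#'   `delta`.
#' @export
setMethod("retainBrainwaves", "SubbandSet", function(x) {
  info <- x@bandInfo
  keep <- !is.na(info$wave) & info$wave != "noise"
  if (sum(keep) != 5L) {
    stop("expected the 5 named brain waves, found ", sum(keep),
         " (is this a 6-level, 256 Hz decomposition?)")
  }
  m <- x@bands[, keep, drop = FALSE]
  colnames(m) <- info$wave[keep]
  m[, .brainwave_order, drop = FALSE]
})

setMethod("show", "SubbandSet", function(object) {
  cat(sprintf(
    "SubbandSet: %d samples x %d bands (%s, %d-level, %s boundary, %g Hz)\n",
    nrow(object@bands), ncol(object@bands), object@wavelet,
    sum(startsWith(object@bandInfo$code, "D")), object@boundary,
    object@samplingRate))
  info <- object@bandInfo
  cat(paste0(
    "  ", info$code, ": ", ifelse(is.na(info$wave), "?", info$wave),
    ifelse(is.na(info$nominalLowHz), "",
           sprintf(" (label %g-%g Hz)", info$nominalLowHz,
                   info$nominalHighHz)),
    sprintf(" [dyadic %g-%g Hz]", info$dyadicLowHz, info$dyadicHighHz),
    collapse = "\n"), "\n")
})
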