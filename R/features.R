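# The ten-feature time-domain bank, signal standardization, feature-matrix
# assembly and min-max scaling.

#' Names of the ten time-domain features
#'
#' In order: average amplitude change (f1), Hjorth activity (f2), absolute
#' square-root sum (f3), clearance factor (f4), RMS (f5), crest factor
#' (f6), shape factor (f7), log detector (f8), Hjorth mobility (f9) and
#' absolute sum (f10).
#'
#' @return character vector of length 10.
#' @export
featureNames <- function() {
  c("aac", "activity", "abs_sqrt_sum", "clearance_factor", "rms",
    "crest_factor", "shape_factor", "log_detector", "mobility", "abs_sum")
}

.popvar <- function(x) mean((x - mean(x))^2)

.signal_var <- function(x, varianceMode) {
  switch(varianceMode,
    population = .popvar(x),
    sample = stats::var(x),
    stop("unknown varianceMode '", varianceMode, "'")
  )
}

#' Standardize a signal to zero mean and unit variance
#'
#' @param x numeric vector of length >= 2.
#' @param varianceMode `"population"` (divide by C, the default, matching
#'   the mean-power reading of Hjorth activity) or `"sample"` (divide by
#'   C - 1).
#' @return numeric vector of the same length with mean 0 and variance 1.
#' @examples
#' standardize(c(1, 3))  # -1, 1 under the population convention
#' @export
standardize <- function(x, varianceMode = c("population", "sample")) {
  varianceMode <- match.arg(varianceMode)
  x <- as.numeric(x)
  if (length(x) < 2L) stop("signal must have at least 2 samples")
  if (any(!is.finite(x))) stop("signal contains non-finite samples")
  v <- .signal_var(x, varianceMode)
  if (v == 0) {
    stop("degenerate input: constant signal has zero variance and ",
         "cannot be standardized")
  }
  (x - mean(x)) / sqrt(v)
}

#' Extract the ten time-domain features from one signal
#'
#' Computes, for a signal s of length C (using the population-variance
#' convention by default, and absolute values inside square roots and
#' logarithms so that standardized signals with negative samples stay
#' real-valued):
#' \describe{
#'   \item{aac (f1)}{`sum(|s[i+1] - s[i]|) / C` -- average amplitude
#'     change, a.k.a. difference absolute mean value.}
#'   \item{activity (f2)}{variance of s (Hjorth activity, mean power).}
#'   \item{abs_sqrt_sum (f3)}{`sum(sqrt(|s|))`.}
#'   \item{clearance_factor (f4)}{`peak / mean(sqrt(|s|))^2`, with
#'     `peak = (max(s) - min(s)) / 2`.}
#'   \item{rms (f5)}{`sqrt(mean(s^2))`.}
#'   \item{crest_factor (f6)}{`peak / rms`.}
#'   \item{shape_factor (f7)}{`rms / mean(|s|)`.}
#'   \item{log_detector (f8)}{`exp(mean(log(|s|)))`; samples with
#'     `|s| < logEps` are clamped to `logEps` so a single zero sample does
#'     not collapse the geometric mean.}
#'   \item{mobility (f9)}{`sd(diff(s)) / sd(s)` (Hjorth mobility, forward
#'     differences); `NaN` with a warning for a constant signal.}
#'   \item{abs_sum (f10)}{`sum(|s|)`.}
#' }
#'
#' @param x numeric vector of length >= 2 with finite values.
#' @param varianceMode `"population"` (default) or `"sample"`; used wherever
#'   a variance or standard deviation appears (f2, f9).
#' @param logEps clamp for `|s|` inside the log detector (default 1e-12).
#' @return named numeric vector of length 10 (see [featureNames()]).
#' @examples
#' extractFeatures(c(0, 1, 0, 1))[["aac"]]  # 0.75
#' @export
extractFeatures <- function(x, varianceMode = c("population", "sample"),
                            logEps = 1e-12) {
  varianceMode <- match.arg(varianceMode)
  x <- as.numeric(x)
  C <- length(x)
  if (C < 2L) stop("signal must have at least 2 samples")
  if (any(!is.finite(x))) stop("signal contains non-finite samples")

  d <- diff(x)
  absx <- abs(x)
  peak <- (max(x) - min(x)) / 2
  rms <- sqrt(mean(x^2))
  meanAbs <- mean(absx)
  meanSqrtAbs <- mean(sqrt(absx))
  va <- .signal_var(x, varianceMode)
  vd <- .signal_var(d, varianceMode)
  if (va == 0) {
    warning("zero-variance signal: mobility (f9) is undefined (NaN)")
  }

  out <- c(
    aac = sum(abs(d)) / C,
    activity = va,
    abs_sqrt_sum = sum(sqrt(absx)),
    clearance_factor = if (meanSqrtAbs > 0) peak / meanSqrtAbs^2 else
      if (peak == 0) 0 else NaN,
    rms = rms,
    crest_factor = if (rms > 0) peak / rms else if (peak == 0) 0 else NaN,
    shape_factor = if (meanAbs > 0) rms / meanAbs else NaN,
    log_detector = exp(mean(log(pmax(absx, logEps)))),
    mobility = if (va > 0) sqrt(vd) / sqrt(va) else NaN,
    abs_sum = sum(absx)
  )
  out
}

#' Build the feature matrix of a segment collection
#'
#' Decomposes every selected segment into subbands, discards the two noise
#' bands, standardizes each retained brain-wave reconstruction to zero mean
#' and unit variance, and extracts the ten features -- one feature-set
#' column per (segment, subband) unit. Column order is deterministic:
#' segments sorted by (subject, emotion, video, segment, channel) with the
#' five bands (gamma, beta, alpha, theta, delta) innermost.
#'
#' Under the full default design, restricting to one channel gives the
#' benchmark feature-matrix geometry: 5280 segments x 5 bands = 26400 units
#' of 10 features.
#'
#' @param dataset an [EEGSegmentSet-class].
#' @param channels channels to keep (default: all in the dataset).
#' @param bands brain waves to keep, subset of
#'   `c("gamma","beta","alpha","theta","delta")` (default: all five).
#' @param standardizeMode where the zero-mean/unit-variance normalization
#'   is applied: `"segment"` (default) standardizes the raw segment before
#'   decomposition, so subband reconstructions keep their relative band
#'   powers; `"subband"` standardizes each subband reconstruction
#'   separately (under which the amplitude features f2/f5/f10 become
#'   uninformative); `"none"` skips normalization.
#' @param varianceMode,logEps passed to [extractFeatures()].
#' @param wavelet,levels passed to [decomposeSegment()].
#' @return an [EEGFeatureSet-class].
#' @export
buildFeatureSet <- function(dataset, channels = NULL, bands = NULL,
                            standardizeMode = c("segment", "subband",
                                                "none"),
                            varianceMode = c("population", "sample"),
                            logEps = 1e-12, wavelet = "db8", levels = 6L) {
  standardizeMode <- match.arg(standardizeMode)
  stopifnot(is(dataset, "EEGSegmentSet"))
  varianceMode <- match.arg(varianceMode)
  cd <- colData(dataset)
  allBands <- .brainwave_order
  if (is.null(channels)) channels <- levels(cd$channel)
  if (is.null(bands)) bands <- allBands
  badCh <- setdiff(channels, levels(cd$channel))
  if (length(badCh)) {
    stop("unknown channel(s): ", paste(badCh, collapse = ", "))
  }
  badB <- setdiff(bands, allBands)
  if (length(badB)) {
    stop("unknown band(s): ", paste(badB, collapse = ", "))
  }
  bands <- allBands[allBands %in% bands]   # canonical order
  keep <- which(cd$channel %in% channels)
  if (!length(keep)) stop("empty selection: no segments match the filters")

  ord <- keep[order(cd$subject[keep], as.integer(cd$emotion[keep]),
                    cd$video[keep], cd$segment[keep],
                    as.integer(cd$channel[keep]))]
  fs <- samplingRate(dataset)
  sm <- assay(dataset, "samples")
  nUnits <- length(ord) * length(bands)
  feat <- matrix(NA_real_, nrow = 10L, ncol = nUnits,
                 dimnames = list(featureNames(), NULL))

  col <- 0L
  for (i in ord) {
    seg <- sm[, i]
    if (standardizeMode == "segment") seg <- standardize(seg, varianceMode)
    sb <- decomposeSegment(seg, samplingRate = fs, wavelet = wavelet,
                           levels = levels)
    bw <- retainBrainwaves(sb)
    for (b in bands) {
      sig <- bw[, b]
      if (standardizeMode == "subband") {
        sig <- standardize(sig, varianceMode)
      }
      col <- col + 1L
      feat[, col] <- extractFeatures(sig, varianceMode, logEps)
    }
  }

  idx <- rep(ord, each = length(bands))
  ucd <- S4Vectors::DataFrame(
    subject = cd$subject[idx],
    emotion = cd$emotion[idx],
    video = cd$video[idx],
    segment = cd$segment[idx],
    channel = cd$channel[idx],
    band = factor(rep(bands, times = length(ord)), levels = allBands)
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feat),
    colData = ucd,
    metadata = c(S4Vectors::metadata(dataset),
                 list(standardizeMode = standardizeMode,
                      varianceMode = varianceMode, logEps = logEps,
                      wavelet = wavelet, levels = levels,
                      boundary = "symmetric"))
  )
  new("EEGFeatureSet", se)
}

#' Feature values and labels of a feature set
#'
#' @name featureValues
#' @param x an [EEGFeatureSet-class].
#' @return `featureValues`: numeric matrix with one row per (segment,
#'   subband) unit and one column per feature; `featureLabels`: the factor
#'   of emotion labels, one per unit.
#' @export
setMethod("featureValues", "EEGFeatureSet", function(x) {
  t(assay(x, "features"))
})

#' @rdname featureValues
#' @export
setMethod("featureLabels", "EEGFeatureSet", function(x) {
  colData(x)$emotion
})

setMethod("show", "EEGFeatureSet", function(object) {
  cd <- colData(object)
  cat(sprintf("EEGFeatureSet: %d units x %d features\n", ncol(object),
              nrow(object)))
  cat("  channels:", paste(intersect(levels(cd$channel),
                                     unique(as.character(cd$channel))),
                           collapse = ", "), "\n")
  cat("  bands:", paste(intersect(levels(cd$band),
                                  unique(as.character(cd$band))),
                        collapse = ", "), "\n")
  cat("  emotions:", paste(levels(cd$emotion), collapse = ", "), "\n")
})

#' Min-max scale feature matrices to the unit interval
#'
#' Scales every column to `[0, 1]` via `(x - min) / (max - min)`. With
#' `mode = "train-only"` (the default) the column statistics come from the
#' training matrix alone and are applied unchanged to the test matrix,
#' whose values may then fall outside `[0, 1]`; this avoids information
#' leaking from test to train. `mode = "full-data"` pools both matrices to
#' fit the statistics first -- the benchmark protocol's order of
#' operations (normalize everything, then split). A constant training
#' column maps to 0.
#'
#' @param train numeric matrix (or [EEGFeatureSet-class] values) used to
#'   fit the per-column ranges.
#' @param test optional matrix scaled with the same statistics.
#' @param mode `"train-only"` or `"full-data"`.
#' @return list with `train`, `test` (NULL if absent) and `ranges` (2 x p
#'   matrix of column minima and maxima).
#' @examples
#' minMaxScale(matrix(c(2, 4, 6), ncol = 1))$train[, 1]  # 0, 0.5, 1
#' @export
minMaxScale <- function(train, test = NULL,
                        mode = c("train-only", "full-data")) {
  mode <- match.arg(mode)
  train <- as.matrix(train)
  if (!nrow(train)) stop("training matrix is empty")
  if (!is.null(test)) {
    test <- as.matrix(test)
    if (ncol(test) != ncol(train)) {
      stop("train and test must have the same columns")
    }
  }
  fitOn <- if (mode == "full-data" && !is.null(test)) {
    rbind(train, test)
  } else {
    train
  }
  lo <- apply(fitOn, 2L, min)
  hi <- apply(fitOn, 2L, max)
  span <- hi - lo
  scale1 <- function(m) {
    out <- sweep(m, 2L, lo, "-")
    out <- sweep(out, 2L, ifelse(span > 0, span, 1), "/")
    out[, span == 0] <- 0
    out
  }
  list(train = scale1(train),
       test = if (is.null(test)) NULL else scale1(test),
       ranges = rbind(min = lo, max = hi))
}

#' Serialize a feature set to delimited text
#'
#' Writes one row per (segment, subband) unit with the provenance columns
#' `subject,emotion,video,segment,channel,band` followed by the ten feature
#' columns, as UTF-8 comma-separated text with dot decimals.
#'
#' @param x an [EEGFeatureSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFeatureSet <- function(x, path) {
  stopifnot(is(x, "EEGFeatureSet"))
  df <- cbind(as.data.frame(colData(x)), as.data.frame(featureValues(x)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature set written by [writeFeatureSet()]
#'
#' @param path file path.
#' @return an [EEGFeatureSet-class] (without design metadata).
#' @export
readFeatureSet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "emotion", "video", "segment", "channel", "band",
            featureNames())
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("feature file lacks column(s): ", paste(miss, collapse = ", "))
  }
  feat <- t(as.matrix(df[, featureNames()]))
  rownames(feat) <- featureNames()
  cd <- S4Vectors::DataFrame(
    subject = as.integer(df$subject),
    emotion = factor(df$emotion, levels = unique(df$emotion)),
    video = as.integer(df$video),
    segment = as.integer(df$segment),
    channel = factor(df$channel, levels = unique(df$channel)),
    band = factor(df$band, levels = .brainwave_order)
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feat), colData = cd)
  new("EEGFeatureSet", se)
}
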