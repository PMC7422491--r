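#' Experimental design of an EEG emotion database
#'
#' Describes the layout of a recording campaign: how many subjects were
#' recorded, which emotions were elicited, how many stimulus videos per
#' emotion, how many stored segments ("pages") per video, the bipolar
#' channels kept for analysis, and the segment geometry. The defaults
#' reproduce the benchmark database design: 44 subjects, four emotions
#' (happy, sad, fear, neutral), 3 videos per emotion, 10 ten-second pages
#' per video at 256 Hz on the four frontal bipolar channels FP2-F4, FP2-F8,
#' FP1-F3 and FP1-F7.
#'
#' @slot nSubjects number of subjects.
#' @slot emotions ordered character vector of emotion labels.
#' @slot videosPerEmotion number of stimulus videos per emotion.
#' @slot segmentsPerVideo number of stored segments per video.
#' @slot channels ordered character vector of bipolar channel names.
#' @slot samplingRate sampling rate in Hz.
#' @slot segmentSeconds segment duration in seconds.
#'
#' @seealso [datasetDesign()] for the user constructor, [segmentLength()]
#'   for the per-segment sample count `C = samplingRate * segmentSeconds`.
#' @exportClass DatasetDesign
setClass("DatasetDesign",
  representation(
    nSubjects = "integer",
    emotions = "character",
    videosPerEmotion = "integer",
    segmentsPerVideo = "integer",
    channels = "character",
    samplingRate = "numeric",
    segmentSeconds = "numeric"
  )
)

setValidity("DatasetDesign", function(object) {
  msg <- character()
  counts <- c(
    nSubjects = object@nSubjects,
    videosPerEmotion = object@videosPerEmotion,
    segmentsPerVideo = object@segmentsPerVideo
  )
  if (any(is.na(counts)) || any(counts < 1L))
    msg <- c(msg, "all design counts must be >= 1")
  if (length(object@emotions) < 1L || anyDuplicated(object@emotions))
    msg <- c(msg, "emotion labels must be non-empty and unique")
  if (length(object@channels) < 1L || anyDuplicated(object@channels))
    msg <- c(msg, "channel names must be non-empty and unique")
  if (!isTRUE(object@samplingRate > 0))
    msg <- c(msg, "samplingRate must be positive")
  if (!isTRUE(object@segmentSeconds > 0))
    msg <- c(msg, "segmentSeconds must be positive")
  C <- object@samplingRate * object@segmentSeconds
  if (length(C) == 1L && is.finite(C) && abs(C - round(C)) > 1e-9 * max(1, C))
    msg <- c(msg, "samplingRate * segmentSeconds must be an integer")
  if (length(msg)) msg else TRUE
})

#' Per-emotion spectral signature for synthetic EEG
#'
#' Parameterises the synthetic generator for one emotion (optionally on one
#' channel): the relative amplitude given to each of the five brain-wave
#' bands, the level of broadband 1/f background noise mixed in, and a
#' per-subject
#' lognormal jitter applied multiplicatively to the band weights. The
#' signature is a modelling stand-in -- the benchmark database never
#' characterises its per-emotion spectra -- but it gives the pipeline
#' controllable, emotion-dependent band-power structure to detect.
#'
#' @slot bandWeights named numeric vector; names drawn from
#'   `c("delta","theta","alpha","beta","gamma")`, values are nonnegative
#'   relative amplitudes (band RMS in units of 10 uV before jitter).
#' @slot noiseLevel nonnegative amplitude of the broadband 1/f (pink)
#'   background noise, on the same scale.
#' @slot subjectSd nonnegative standard deviation (log scale) of the
#'   per-subject lognormal multiplier applied to `bandWeights`.
#'
#' @seealso [emotionSignature()], [presetSignatures()]
#' @exportClass EmotionSignature
setClass("EmotionSignature",
  representation(
    bandWeights = "numeric",
    noiseLevel = "numeric",
    subjectSd = "numeric"
  )
)

setValidity("EmotionSignature", function(object) {
  msg <- character()
  known <- c("delta", "theta", "alpha", "beta", "gamma")
  w <- object@bandWeights
  if (is.null(names(w)) || !all(names(w) %in% known))
    msg <- c(msg, sprintf(
      "band weight names must be drawn from {%s}",
      paste(known, collapse = ", ")
    ))
  if (anyDuplicated(names(w)))
    msg <- c(msg, "duplicated band name in bandWeights")
  if (any(!is.finite(w)) || any(w < 0))
    msg <- c(msg, "band weights must be finite and nonnegative")
  if (!isTRUE(object@noiseLevel >= 0))
    msg <- c(msg, "noiseLevel must be nonnegative")
  if (!isTRUE(object@subjectSd >= 0))
    msg <- c(msg, "subjectSd must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Collection of labeled EEG segments
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' `"samples"` holds one segment per column (C rows, one per sample point)
#' and whose `colData` carries the provenance of every segment: `subject`,
#' `emotion`, `video`, `segment` and `channel`. The design that produced the
#' collection (and, for synthetic data, the generator seed) is stored in
#' `metadata()`.
#'
#' @seealso [generateDataset()], [buildFeatureSet()]
#' @exportClass EEGSegmentSet
setClass("EEGSegmentSet", contains = "SummarizedExperiment")

setValidity("EEGSegmentSet", function(object) {
  msg <- character()
  if (!"samples" %in% assayNames(object))
    msg <- c(msg, "assay 'samples' is required")
  need <- c("subject", "emotion", "video", "segment", "channel")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Subband decomposition of one EEG segment
#'
#' Time-domain reconstructions of the seven subbands of a six-level
#' Daubechies-8 wavelet decomposition at 256 Hz: D1 (noise, 125-256 Hz),
#' D2 (noise, 63-125 Hz), D3 (gamma, 30-63 Hz), D4 (beta, 13-30 Hz),
#' D5 (alpha, 8-13 Hz), D6 (theta, 4-7 Hz) and A6 (delta, 0-4 Hz). Each
#' reconstruction has the length of the input segment and the seven sum to
#' the input (perfect reconstruction). The Hz ranges are the conventional
#' display labels; the actual dyadic band edges at 256 Hz are
#' 128/64/32/16/8/4 Hz.
#'
#' @slot bands numeric matrix, one column per subband (D1..D6, A6), one row
#'   per sample point.
#' @slot bandInfo data.frame mapping subband code to brain-wave name and
#'   nominal Hz range.
#' @slot samplingRate sampling rate of the decomposed segment, Hz.
#' @slot wavelet wavelet name (currently `"db8"`).
#' @slot boundary boundary-extension mode used by the transform.
#'
#' @seealso [decomposeSegment()], [retainBrainwaves()]
#' @exportClass SubbandSet
setClass("SubbandSet",
  representation(
    bands = "matrix",
    bandInfo = "data.frame",
    samplingRate = "numeric",
    wavelet = "character",
    boundary = "character"
  )
)

setValidity("SubbandSet", function(object) {
  msg <- character()
  if (ncol(object@bands) != nrow(object@bandInfo))
    msg <- c(msg, "one bandInfo row per band column is required")
  if (!identical(colnames(object@bands), object@bandInfo$code))
    msg <- c(msg, "band column names must match bandInfo$code")
  if (length(msg)) msg else TRUE
})

#' Feature matrix with provenance
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' `"features"` holds the ten time-domain features (rows) for every
#' (segment, subband) unit (columns). `colData` carries `subject`,
#' `emotion`, `video`, `segment`, `channel` and `band` for each unit.
#'
#' @seealso [buildFeatureSet()], [featureValues()], [featureLabels()]
#' @exportClass EEGFeatureSet
setClass("EEGFeatureSet", contains = "SummarizedExperiment")

setValidity("EEGFeatureSet", function(object) {
  msg <- character()
  if (!"features" %in% assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  if (nrow(object) != 10L)
    msg <- c(msg, "exactly 10 feature rows are required")
  need <- c("subject", "emotion", "video", "segment", "channel", "band")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Fitted extreme learning machine
#'
#' Immutable container for a trained ELM: the random hidden layer (input
#' weights `alpha`, one row per hidden node, and biases `beta`), the learned
#' output weights `gammaOut` (one column per class), the ordered class list,
#' and the fitting metadata (hidden-node count, RNG seed, optional ridge
#' penalty, and the singular-value cutoff used by the pseudoinverse).
#'
#' @slot alpha numeric matrix, k x d hidden input weights.
#' @slot beta numeric vector of k hidden biases.
#' @slot gammaOut numeric matrix, k x nClasses output weights.
#' @slot classes ordered character vector of class labels.
#' @slot k number of hidden nodes.
#' @slot seed RNG seed that generated the hidden layer.
#' @slot ridge ridge penalty used in the solve (0 = plain pseudoinverse).
#' @slot svCutoff singular values below this were treated as zero.
#'
#' @seealso [elmFit()], [elmPredict()]
#' @exportClass ElmModel
setClass("ElmModel",
  representation(
    alpha = "matrix",
    beta = "numeric",
    gammaOut = "matrix",
    classes = "character",
    k = "integer",
    seed = "integer",
    ridge = "numeric",
    svCutoff = "numeric"
  )
)

setValidity("ElmModel", function(object) {
  msg <- character()
  k <- object@k
  if (!isTRUE(k >= 1L)) msg <- c(msg, "k must be >= 1")
  if (nrow(object@alpha) != k) msg <- c(msg, "alpha must have k rows")
  if (length(object@beta) != k) msg <- c(msg, "beta must have length k")
  if (nrow(object@gammaOut) != k) msg <- c(msg, "gammaOut must have k rows")
  if (ncol(object@gammaOut) != length(object@classes))
    msg <- c(msg, "gammaOut must have one column per class")
  if (length(object@classes) < 1L) msg <- c(msg, "classes must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Classification metrics derived from a confusion matrix
#'
#' Holds the raw confusion matrix (rows = true class, columns = predicted)
#' plus the one-vs-rest metrics per class (sensitivity/recall, specificity,
#' precision, F1), the overall accuracy, and macro/micro aggregates. For
#' single-label multiclass problems micro-averaged sensitivity equals the
#' accuracy; both are reported.
#'
#' @slot confusion integer matrix of counts, true class in rows.
#' @slot perClass data.frame of one-vs-rest metrics, one row per class; the
#'   `flagged` column marks classes where a 0/0 ratio was reported as 0.
#' @slot accuracy overall accuracy, trace/total.
#' @slot macro named numeric, unweighted means of the per-class metrics.
#' @slot micro named numeric, metrics computed from pooled counts.
#'
#' @seealso [metricsFromConfusion()]
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(
    confusion = "matrix",
    perClass = "data.frame",
    accuracy = "numeric",
    macro = "numeric",
    micro = "numeric"
  )
)

setValidity("MetricsReport", function(object) {
  msg <- character()
  conf <- object@confusion
  if (nrow(conf) != ncol(conf)) msg <- c(msg, "confusion must be square")
  if (any(conf < 0)) msg <- c(msg, "confusion counts must be nonnegative")
  total <- sum(conf)
  if (total > 0 &&
      abs(object@accuracy - sum(diag(conf)) / total) > 1e-12)
    msg <- c(msg, "accuracy must equal trace(confusion)/total")
  if (nrow(object@perClass) != nrow(conf))
    msg <- c(msg, "one perClass row per class is required")
  if (length(msg)) msg else TRUE
})

#' Train/test split specification
#'
#' @slot trainFraction proportion of rows assigned to the training set
#'   (default 0.70).
#' @slot stratified whether the split preserves per-class proportions.
#' @slot seed RNG seed of the permutation.
#'
#' @seealso [splitSpec()], [stratifiedSplit()]
#' @exportClass SplitSpec
setClass("SplitSpec",
  representation(
    trainFraction = "numeric",
    stratified = "logical",
    seed = "integer"
  )
)

setValidity("SplitSpec", function(object) {
  if (!isTRUE(object@trainFraction > 0 && object@trainFraction < 1))
    return("trainFraction must lie strictly between 0 and 1")
  TRUE
})
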