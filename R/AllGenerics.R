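#' @name design-accessors
#' @title Accessors for DatasetDesign
#' @description Read the components of a [DatasetDesign-class]:
#' subject/video/segment counts, emotion and channel label sets, sampling
#' rate, segment duration, and the derived per-segment sample count
#' `segmentLength(x) = samplingRate(x) * segmentSeconds(x)`.
#' @param x a [DatasetDesign-class] (for `samplingRate` also an
#'   [EEGSegmentSet-class] or [SubbandSet-class]).
#' @return the requested component; `segmentLength` returns an integer.
#' @examples
#' d <- datasetDesign()
#' nSubjects(d)
#' segmentLength(d)  # 2560 samples: 256 Hz x 10 s
NULL

#' @rdname design-accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname design-accessors
#' @export
setGeneric("videosPerEmotion",
  function(x) standardGeneric("videosPerEmotion"))

#' @rdname design-accessors
#' @export
setGeneric("segmentsPerVideo",
  function(x) standardGeneric("segmentsPerVideo"))

#' @rdname design-accessors
#' @export
setGeneric("emotionLabels", function(x) standardGeneric("emotionLabels"))

#' @rdname design-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname design-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname design-accessors
#' @export
setGeneric("segmentSeconds", function(x) standardGeneric("segmentSeconds"))

#' @rdname design-accessors
#' @export
setGeneric("segmentLength", function(x) standardGeneric("segmentLength"))

#' @rdname bandSignals
#' @export
setGeneric("bandSignals", function(x, ...) standardGeneric("bandSignals"))

#' @rdname retainBrainwaves
#' @export
setGeneric("retainBrainwaves",
  function(x) standardGeneric("retainBrainwaves"))

#' @rdname featureValues
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname featureValues
#' @export
setGeneric("featureLabels", function(x) standardGeneric("featureLabels"))

#' @name metrics-accessors
#' @title Accessors for MetricsReport
#' @description Read the components of a [MetricsReport-class]: the overall
#' accuracy, the per-class one-vs-rest metric table, the macro (unweighted
#' mean over classes) and micro (pooled counts) aggregates, and the raw
#' confusion matrix.
#' @param x a [MetricsReport-class].
#' @return `accuracy`: a scalar; `perClassMetrics`: a data.frame;
#'   `macroMetrics`, `microMetrics`: named numeric vectors; `confusion`:
#'   an integer matrix with true classes in rows.
NULL

#' @rdname metrics-accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname metrics-accessors
#' @export
setGeneric("perClassMetrics",
  function(x) standardGeneric("perClassMetrics"))

#' @rdname metrics-accessors
#' @export
setGeneric("macroMetrics", function(x) standardGeneric("macroMetrics"))

#' @rdname metrics-accessors
#' @export
setGeneric("microMetrics", function(x) standardGeneric("microMetrics"))

#' @rdname metrics-accessors
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))

#' @rdname channelWiseExperiment
#' @export
setGeneric("channelWiseExperiment",
  function(x, config = runConfig(), ...)
    standardGeneric("channelWiseExperiment"))

#' @rdname subbandWiseExperiment
#' @export
setGeneric("subbandWiseExperiment",
  function(x, config = runConfig(), ...)
    standardGeneric("subbandWiseExperiment"))

#' @rdname emotionWiseExperiment
#' @export
setGeneric("emotionWiseExperiment",
  function(x, channel, band, config = runConfig(), ...)
    standardGeneric("emotionWiseExperiment"))
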