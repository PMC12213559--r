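## Constructors, accessors and show() methods.

#' Construct an EEGRecord
#'
#' @param data numeric matrix, channels x samples.
#' @param samplingRate sampling rate in Hz.
#' @param channelNames optional channel labels; defaults to Ch1..ChC.
#' @param subjectId subject identifier.
#' @param label integer class label (0 or 1).
#' @return an [EEGRecord-class].
#' @examples
#' rec <- eegRecord(matrix(rnorm(400), 4, 100), 100)
#' samplingRate(rec)
#' @export
eegRecord <- function(data, samplingRate, channelNames = NULL,
                      subjectId = "s01", label = 0L) {
  if (is.null(channelNames)) channelNames <- paste0("Ch", seq_len(nrow(data)))
  new("EEGRecord", data = data, samplingRate = as.numeric(samplingRate),
      channelNames = as.character(channelNames),
      subjectId = as.character(subjectId), label = as.integer(label))
}

#' Construct a SegmentSet
#'
#' @param segments numeric array (N x C x 1 x T); an (N x C x T) array is
#'   accepted and the singleton axis inserted.
#' @param labels integer vector of class labels (0/1), length N.
#' @param subjectIds character vector of subject identifiers, length N.
#' @param samplingRate sampling rate in Hz.
#' @return a [SegmentSet-class].
#' @export
segmentSet <- function(segments, labels, subjectIds, samplingRate) {
  d <- dim(segments)
  if (length(d) == 3L) {
    segments <- array(segments, dim = c(d[1], d[2], 1L, d[3]))
  }
  new("SegmentSet", segments = segments, labels = as.integer(labels),
      subjectIds = as.character(subjectIds),
      samplingRate = as.numeric(samplingRate))
}

#' @describeIn segmentSet segment array accessor.
#' @param x a SegmentSet.
#' @export
setMethod("segments", "SegmentSet", function(x) x@segments)

#' @describeIn segmentSet number of segments.
#' @export
setMethod("nSegments", "SegmentSet", function(x) dim(x@segments)[1])

#' @describeIn segmentSet per-segment labels.
#' @param object a SegmentSet.
#' @export
setMethod("labels", "SegmentSet", function(object) object@labels)

#' @describeIn segmentSet per-segment subject identifiers.
#' @export
setMethod("subjectIds", "SegmentSet", function(x) x@subjectIds)

#' @describeIn segmentSet sampling rate in Hz.
#' @export
setMethod("samplingRate", "SegmentSet", function(x) x@samplingRate)

#' Subset a SegmentSet by segment index
#'
#' @param x a [SegmentSet-class].
#' @param i integer or logical index over segments.
#' @param j,...,drop ignored.
#' @return a [SegmentSet-class] with the selected segments.
#' @export
setMethod("[", "SegmentSet", function(x, i, j, ..., drop = FALSE) {
  segmentSet(x@segments[i, , , , drop = FALSE], x@labels[i],
             x@subjectIds[i], x@samplingRate)
})

setMethod("show", "SegmentSet", function(object) {
  d <- dim(object@segments)
  cat(sprintf("SegmentSet: %d segments, %d channels, T = %d @ %g Hz\n",
              d[1], d[2], d[4], object@samplingRate))
  tab <- table(factor(object@labels, levels = c(0L, 1L)))
  cat(sprintf("  labels: %d x class 0, %d x class 1; %d subjects\n",
              tab[["0"]], tab[["1"]], length(unique(object@subjectIds))))
  invisible(object)
})

#' @describeIn eegRecord signal matrix accessor.
#' @param x an EEGRecord.
#' @export
setMethod("signalData", "EEGRecord", function(x) x@data)

#' @describeIn eegRecord sampling rate in Hz.
#' @export
setMethod("samplingRate", "EEGRecord", function(x) x@samplingRate)

#' @describeIn eegRecord channel labels.
#' @export
setMethod("channelNames", "EEGRecord", function(x) x@channelNames)

#' @describeIn eegRecord per-record subject identifier.
#' @export
setMethod("subjectIds", "EEGRecord", function(x) x@subjectId)

#' @describeIn eegRecord class label (0/1).
#' @param object an EEGRecord.
#' @export
setMethod("labels", "EEGRecord", function(object) object@label)

setMethod("show", "EEGRecord", function(object) {
  cat(sprintf(
    "EEGRecord '%s' (label %d): %d channels x %d samples @ %g Hz\n",
    object@subjectId, object@label, nrow(object@data), ncol(object@data),
    object@samplingRate))
  invisible(object)
})

setMethod("show", "StandardizationStats", function(object) {
  cat(sprintf(
    "StandardizationStats over T = %d time points (epsilon = %g)\n",
    length(object@mu), object@epsilon))
  cat(sprintf("  mu in [%.4g, %.4g]; sigma in [%.4g, %.4g]\n",
              min(object@mu), max(object@mu), min(object@sigma),
              max(object@sigma)))
  invisible(object)
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    paste0("SyntheticSpec: 2 x %d subjects x %d segments, %d ch, T = %d ",
           "@ %g Hz\n  band %g-%g Hz, power ratio %g, seed %d\n"),
    object@nSubjectsPerClass, object@segmentsPerSubject, object@nChannels,
    object@segmentLength, object@samplingRate, object@targetBand[1],
    object@targetBand[2], object@powerRatio, object@seed))
  invisible(object)
})

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig (DSCnet)\n")
  cat(sprintf("  input: %d channels; embedding: %s (width %d -> hybrid %d)\n",
              object@inChannels,
              if (object@useEmbedding) "on" else "off",
              object@embedWidth, 2L * object@embedWidth))
  cat(sprintf(
    "  stage 2: %d round(s) @ width %d, conv = %s, DAFM = %s (n_levels %d), CoT = %s (k = %d, groups %d)\n",
    object@rounds, object@stage2Width, object@convType,
    if (object@useDafm) "on" else "off", object@nLevels,
    if (object@useCot) "on" else "off", object@cotKernel, object@cotGroups))
  cat(sprintf("  classifier: hidden %d -> %d classes\n",
              object@classifierHidden, object@nClasses))
  invisible(object)
})

#' @describeIn dscnetConfig configuration of a parameter store.
#' @param x a ParameterStore.
#' @export
setMethod("modelConfig", "ParameterStore", function(x) x@config)

setMethod("show", "ParameterStore", function(object) {
  cat(sprintf("ParameterStore: %d learnable parameters (%s init, seed %d)\n",
              sum(rapply(object@weights, length, how = "unlist")),
              object@scheme, object@seed))
  invisible(object)
})

#' @describeIn makeSplit training-set indices.
#' @export
setMethod("trainIndices", "SplitPlan", function(x) x@trainIndices)

#' @describeIn makeSplit test-set indices.
#' @export
setMethod("testIndices", "SplitPlan", function(x) x@testIndices)

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan (%s, train fraction %g, seed %d): %d train / %d test\n",
              object@mode, object@trainFraction, object@seed,
              length(object@trainIndices), length(object@testIndices)))
  invisible(object)
})

#' @describeIn computeMetrics overall accuracy accessor.
#' @param x an EvalReport.
#' @export
setMethod("accuracy", "EvalReport", function(x) x@accuracy)

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport", if (nzchar(object@splitDescriptor))
    sprintf("(%s)", object@splitDescriptor) else "", "\n")
  cat(sprintf(
    "  accuracy %.2f%% | weighted P %.2f%% R %.2f%% F1 %.2f%% | macro F1 %.2f%%\n",
    100 * object@accuracy, 100 * object@weighted[["precision"]],
    100 * object@weighted[["recall"]], 100 * object@weighted[["f1"]],
    100 * object@macro[["f1"]]))
  print(object@perClass, row.names = FALSE, digits = 4)
  invisible(object)
})

setMethod("show", "UCITrialRecord", function(object) {
  cat(sprintf(
    "UCITrialRecord %s trial %d (%s, label %d): %d channels x %d samples\n",
    object@subjectId, object@trialNumber, object@condition, object@label,
    nrow(object@data), ncol(object@data)))
  invisible(object)
})
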