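## S4 containers for the whole pipeline: raw recordings, segment stacks,
## standardization statistics, model configuration/parameters, split plans
## and evaluation reports.

#' One subject's multichannel EEG recording
#'
#' Holds a continuous (channels x samples) signal together with its sampling
#' rate, channel labels, subject identifier and binary class label
#' (0 = control, 1 = case).  Amplitude units are arbitrary but must be
#' consistent across channels.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelNames character vector of channel labels (possibly empty;
#'   when non-empty its length must equal the channel count).
#' @slot subjectId subject identifier.
#' @slot label integer class label in \{0, 1\}.
#'
#' @seealso [eegRecord()] for the user-facing constructor.
#' @export
setClass("EEGRecord",
  representation(
    data = "matrix",
    samplingRate = "numeric",
    channelNames = "character",
    subjectId = "character",
    label = "integer"
  )
)

setValidity("EEGRecord", function(object) {
  msg <- character(0)
  if (nrow(object@data) < 1L || ncol(object@data) < 1L)
    msg <- c(msg, "data must have at least one channel and one sample")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@channelNames) > 0L &&
      length(object@channelNames) != nrow(object@data))
    msg <- c(msg, "channelNames length must equal the channel count")
  if (!object@label %in% c(0L, 1L))
    msg <- c(msg, "label must be 0 or 1")
  if (anyNA(object@data) || !all(is.finite(object@data)))
    msg <- c(msg, "data must be finite")
  if (length(msg)) msg else TRUE
})

#' A stack of fixed-length EEG segments
#'
#' The dataset unit consumed by the model: an (N x C x 1 x T) array of
#' segments with per-segment labels and subject identifiers.  The singleton
#' third axis is the fixed "height" of the (C x 1 x T) layout used
#' throughout the network.
#'
#' @slot segments numeric array with dimensions (N, C, 1, T).
#' @slot labels integer vector of length N with values in \{0, 1\}.
#' @slot subjectIds character vector of length N.
#' @slot samplingRate sampling rate in Hz.
#'
#' @seealso [segmentSet()], [generateDataset()], [segmentRecord()]
#' @export
setClass("SegmentSet",
  representation(
    segments = "array",
    labels = "integer",
    subjectIds = "character",
    samplingRate = "numeric"
  )
)

setValidity("SegmentSet", function(object) {
  msg <- character(0)
  d <- dim(object@segments)
  if (length(d) != 4L || d[3] != 1L)
    msg <- c(msg, "segments must be an (N x C x 1 x T) array")
  if (length(object@labels) != d[1])
    msg <- c(msg, "labels length must equal the number of segments")
  if (length(object@subjectIds) != d[1])
    msg <- c(msg, "subjectIds length must equal the number of segments")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 or 1")
  if (anyNA(object@segments) || !all(is.finite(object@segments)))
    msg <- c(msg, "segments must be finite")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  ## a subject must not appear with two different labels
  if (length(object@labels)) {
    bySub <- split(object@labels, object@subjectIds)
    if (any(vapply(bySub, function(l) length(unique(l)) > 1L, logical(1))))
      msg <- c(msg, "a subject carries more than one label")
  }
  if (length(msg)) msg else TRUE
})

#' Per-time-point standardization statistics
#'
#' For every time point t of a segment the cross-channel mean and standard
#' deviation are computed per segment and averaged over the training
#' segments, giving global curves mu(t) and sigma(t).  Standardization maps
#' x to (x - mu(t)) / max(sigma(t), epsilon).
#'
#' @slot mu numeric vector of length T.
#' @slot sigma numeric vector of length T (non-negative).
#' @slot epsilon small positive guard applied as a floor on sigma.
#'
#' @seealso [fitStandardization()], [standardize()]
#' @export
setClass("StandardizationStats",
  representation(mu = "numeric", sigma = "numeric", epsilon = "numeric")
)

setValidity("StandardizationStats", function(object) {
  msg <- character(0)
  if (length(object@mu) != length(object@sigma))
    msg <- c(msg, "mu and sigma must have equal length")
  if (any(object@sigma < 0)) msg <- c(msg, "sigma entries must be >= 0")
  if (length(object@epsilon) != 1L || object@epsilon <= 0)
    msg <- c(msg, "epsilon must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic two-class EEG dataset
#'
#' Describes the simulated cohort: class-balanced subjects, each
#' contributing a fixed number of fixed-length eyes-closed-style segments of
#' multichannel band-limited noise.  Class 1 carries oscillatory power in
#' `targetBand` elevated by `powerRatio` over class 0; everything else is
#' shared.  Identical (spec, seed) pairs yield bit-identical data.
#'
#' @slot nSubjectsPerClass subjects per class.
#' @slot segmentsPerSubject segments per subject.
#' @slot nChannels channel count.
#' @slot samplingRate sampling rate in Hz.
#' @slot segmentLength segment length in samples.
#' @slot targetBand numeric length-2, oscillation band (low, high) in Hz.
#' @slot powerRatio class-1 / class-0 band-power ratio, >= 1.
#' @slot noiseFloor RMS amplitude of the 1/f background (and of the class-0
#'   oscillation source, which is expressed on the same scale).
#' @slot lineNoiseAmplitude amplitude of an optional 50 Hz mains component.
#' @slot driftAmplitude amplitude of an optional sub-0.5 Hz drift component.
#' @slot seed integer RNG seed.
#'
#' @seealso [syntheticSpec()], [generateDataset()], [generateRawRecording()]
#' @export
setClass("SyntheticSpec",
  representation(
    nSubjectsPerClass = "integer",
    segmentsPerSubject = "integer",
    nChannels = "integer",
    samplingRate = "numeric",
    segmentLength = "integer",
    targetBand = "numeric",
    powerRatio = "numeric",
    noiseFloor = "numeric",
    lineNoiseAmplitude = "numeric",
    driftAmplitude = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character(0)
  if (object@nSubjectsPerClass < 1L) msg <- c(msg, "nSubjectsPerClass must be >= 1")
  if (object@segmentsPerSubject < 1L) msg <- c(msg, "segmentsPerSubject must be >= 1")
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  if (length(object@targetBand) != 2L || object@targetBand[1] <= 0 ||
      object@targetBand[2] <= object@targetBand[1] ||
      object@targetBand[2] >= object@samplingRate / 2)
    msg <- c(msg, "targetBand must satisfy 0 < low < high < samplingRate/2")
  if (object@powerRatio < 1) msg <- c(msg, "powerRatio must be >= 1")
  if (length(object@targetBand) == 2L && object@targetBand[1] > 0 &&
      object@segmentLength < 2 * object@samplingRate / object@targetBand[1])
    msg <- c(msg, "segmentLength must fit at least two cycles of targetBand[1]")
  if (object@noiseFloor < 0 || object@lineNoiseAmplitude < 0 ||
      object@driftAmplitude < 0)
    msg <- c(msg, "amplitudes must be non-negative")
  if (length(msg)) msg else TRUE
})

#' DSCnet architecture configuration
#'
#' Every structural hyperparameter of the network.  The canonical settings
#' are two DAFM scale levels, two stage-2 feature-extraction rounds and
#' 1 x 3 temporal kernels; layer widths and the remaining knobs are open
#' choices exposed here.
#'
#' @slot inChannels input channel count C.
#' @slot embedWidth per-branch stage-1 width (the hybrid representation has
#'   2 * embedWidth channels).
#' @slot stage2Width channel width inside stage 2.
#' @slot nLevels DAFM scale divisions (2 canonical, 4 as ablation).
#' @slot dafmPool temporal pooling factor of DAFM level j (factor
#'   `dafmPool^j`, capped at the time length).
#' @slot cotKernel temporal kernel size k of the CoT group convolution and
#'   of its attention neighbourhood.
#' @slot cotGroups group count of the CoT static-context convolution.
#' @slot rounds number of stage-2 rounds (independent weights per round).
#' @slot maxpoolSize temporal max-pooling factor closing each round.
#' @slot classifierHidden width of the classifier's hidden 1 x 1 layer.
#' @slot nClasses number of output classes.
#' @slot activation activation label (only "gelu" is implemented).
#' @slot useEmbedding include the stage-1 hybrid embedding.
#' @slot convType "dsc" for depthwise-separable, "sc" for a standard dense
#'   1 x 3 convolution (ablation).
#' @slot useDafm include the DAFM branch.
#' @slot useCot include the CoT attention branch.
#' @slot useStage2 include stage 2 at all (classifier-only diagnostic when
#'   FALSE).
#'
#' @seealso [dscnetConfig()]
#' @export
setClass("ModelConfig",
  representation(
    inChannels = "integer",
    embedWidth = "integer",
    stage2Width = "integer",
    nLevels = "integer",
    dafmPool = "integer",
    cotKernel = "integer",
    cotGroups = "integer",
    rounds = "integer",
    maxpoolSize = "integer",
    classifierHidden = "integer",
    nClasses = "integer",
    activation = "character",
    useEmbedding = "logical",
    convType = "character",
    useDafm = "logical",
    useCot = "logical",
    useStage2 = "logical"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character(0)
  counts <- c(
    inChannels = object@inChannels, embedWidth = object@embedWidth,
    stage2Width = object@stage2Width, nLevels = object@nLevels,
    dafmPool = object@dafmPool, cotKernel = object@cotKernel,
    cotGroups = object@cotGroups, rounds = object@rounds,
    maxpoolSize = object@maxpoolSize,
    classifierHidden = object@classifierHidden, nClasses = object@nClasses
  )
  if (any(counts < 1L))
    msg <- c(msg, paste("non-positive count:",
                        paste(names(counts)[counts < 1L], collapse = ", ")))
  if (object@useDafm && object@stage2Width %% object@nLevels != 0L)
    msg <- c(msg, "stage2Width must be divisible by nLevels")
  if (object@useCot && object@stage2Width %% object@cotGroups != 0L)
    msg <- c(msg, "stage2Width must be divisible by cotGroups")
  if (object@cotKernel %% 2L != 1L)
    msg <- c(msg, "cotKernel must be odd")
  if (!identical(object@activation, "gelu"))
    msg <- c(msg, "only the 'gelu' activation is implemented")
  if (!object@convType %in% c("dsc", "sc"))
    msg <- c(msg, "convType must be 'dsc' or 'sc'")
  if (length(msg)) msg else TRUE
})

#' Trained (or freshly initialized) model parameters
#'
#' A named, nested collection of kernel weights and biases for every layer
#' of a [ModelConfig-class], plus the non-learned batch-normalization
#' running statistics, the initialization scheme and the seed it was drawn
#' with.
#'
#' @slot weights nested named list of numeric arrays (learnable).
#' @slot state nested named list of batch-norm running means/variances.
#' @slot config the [ModelConfig-class] the shapes belong to.
#' @slot seed integer initialization seed.
#' @slot scheme initialization scheme label.
#'
#' @seealso [initParameters()], [saveCheckpoint()], [loadCheckpoint()]
#' @export
setClass("ParameterStore",
  representation(
    weights = "list",
    state = "list",
    config = "ModelConfig",
    seed = "integer",
    scheme = "character"
  )
)

#' Training hyperparameters
#'
#' @slot epochs number of passes over the training data.
#' @slot batchSize minibatch size.
#' @slot learningRate Adam step size.
#' @slot optimizer optimizer label (only "adam" is implemented).
#' @slot loss loss label (only "cross_entropy" is implemented).
#' @slot lrSchedule "cosine" (decay to 0 over the epoch budget) or
#'   "constant".
#' @slot weightDecay decoupled (AdamW-style) weight-decay coefficient.
#' @slot seed integer seed controlling initialization and data order.
#' @slot earlyStopPatience epochs without improvement of the monitored
#'   quantity (validation accuracy when a validation set exists, training
#'   loss otherwise) before stopping, or NA to disable.
#'
#' @seealso [trainConfig()], [trainDscnet()]
#' @export
setClass("TrainConfig",
  representation(
    epochs = "integer",
    batchSize = "integer",
    learningRate = "numeric",
    lrSchedule = "character",
    weightDecay = "numeric",
    optimizer = "character",
    loss = "character",
    seed = "integer",
    earlyStopPatience = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character(0)
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@learningRate < 0) msg <- c(msg, "learningRate must be >= 0")
  if (object@weightDecay < 0) msg <- c(msg, "weightDecay must be >= 0")
  if (!object@lrSchedule %in% c("cosine", "constant"))
    msg <- c(msg, "lrSchedule must be 'cosine' or 'constant'")
  if (!identical(object@optimizer, "adam"))
    msg <- c(msg, "only the 'adam' optimizer is implemented")
  if (!identical(object@loss, "cross_entropy"))
    msg <- c(msg, "only the 'cross_entropy' loss is implemented")
  if (length(msg)) msg else TRUE
})

#' Train/test split plan
#'
#' Either `per_subject_segments` (80 percent of every subject's segments in
#' train) or `subject_wise` (80 percent of subjects, stratified by class,
#' wholly in train — the stricter, leakage-free protocol and the default
#' everywhere in this package).
#'
#' @slot mode "per_subject_segments" or "subject_wise".
#' @slot trainFraction fraction assigned to training.
#' @slot seed integer seed.
#' @slot trainIndices,testIndices disjoint 1-based segment indices jointly
#'   covering the dataset.
#'
#' @seealso [makeSplit()]
#' @export
setClass("SplitPlan",
  representation(
    mode = "character",
    trainFraction = "numeric",
    seed = "integer",
    trainIndices = "integer",
    testIndices = "integer"
  )
)

setValidity("SplitPlan", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("per_subject_segments", "subject_wise"))
    msg <- c(msg, "mode must be 'per_subject_segments' or 'subject_wise'")
  if (length(intersect(object@trainIndices, object@testIndices)))
    msg <- c(msg, "train and test indices must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Classification evaluation report
#'
#' Confusion counts and accuracy / precision / recall / F1 for a binary
#' task, reported per class and aggregated by support-weighted and macro
#' averaging.  Accuracy is (TP + TN) / (TP + TN + FP + FN) exactly;
#' zero-denominator precision/recall/F1 return 0 for the affected class.
#'
#' @slot perClass data.frame with one row per class: class, support, tp,
#'   fp, fn, tn, precision, recall, f1.
#' @slot accuracy overall accuracy in \[0, 1\].
#' @slot weighted named numeric: support-weighted precision, recall, f1.
#' @slot macro named numeric: macro precision, recall, f1.
#' @slot averaging default averaging reported by accessors ("weighted").
#' @slot splitDescriptor free-text description of the evaluated split.
#' @slot seed integer seed associated with the run (NA if none).
#'
#' @seealso [computeMetrics()], [evaluateModel()]
#' @export
setClass("EvalReport",
  representation(
    perClass = "data.frame",
    accuracy = "numeric",
    weighted = "numeric",
    macro = "numeric",
    averaging = "character",
    splitDescriptor = "character",
    seed = "integer"
  )
)

#' One trial of the UCI alcoholism EEG corpus
#'
#' A parsed trial in the UCI text dialect with the X / Y / nd channels
#' removed, the subject's group decoded from the subject identifier
#' (1 = alcoholic, 0 = control) and all retained channels holding equal
#' sample counts.
#'
#' @slot subjectId subject/file identifier (e.g. "co2a0000364").
#' @slot trialNumber trial index.
#' @slot condition matching-condition label from the trial header.
#' @slot label integer group label (1 alcoholic, 0 control).
#' @slot data numeric matrix, channels x samples.
#' @slot channelNames retained channel labels.
#' @slot samplingRate sampling rate in Hz (256 for this corpus).
#'
#' @seealso [readUciTrial()], [toSegmentSet()]
#' @export
setClass("UCITrialRecord",
  representation(
    subjectId = "character",
    trialNumber = "integer",
    condition = "character",
    label = "integer",
    data = "matrix",
    channelNames = "character",
    samplingRate = "numeric"
  )
)

setValidity("UCITrialRecord", function(object) {
  msg <- character(0)
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, "channelNames must match the channel count")
  if (any(tolower(object@channelNames) %in% c("x", "y", "nd")))
    msg <- c(msg, "excluded channels (X, Y, nd) must not be present")
  if (length(msg)) msg else TRUE
})
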