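## Single-file array containers for SegmentSet / EEGRecord and model
## checkpoints.  The on-disk layout is a flat named list (data, labels,
## subject_ids, sampling_rate, version) serialized with R's native
## serializer; round-trips are bit-exact.

containerVersion <- 1L

#' Write / read a SegmentSet container
#'
#' The container holds the datasets `data` (N x C x 1 x T), `labels` (N),
#' `subject_ids` (N) and the attributes `sampling_rate` and `version` in a
#' single file.  `readSegmentSet(writeSegmentSet(x, p))` is lossless.
#'
#' @param x a [SegmentSet-class].
#' @param path file path.
#' @return `writeSegmentSet` returns `path` invisibly; `readSegmentSet`
#'   returns the [SegmentSet-class].
#' @export
writeSegmentSet <- function(x, path) {
  stopifnot(is(x, "SegmentSet"))
  saveRDS(list(data = x@segments, labels = x@labels,
               subject_ids = x@subjectIds, sampling_rate = x@samplingRate,
               version = containerVersion, kind = "segment_set"),
          path, version = 3)
  invisible(path)
}

#' @rdname writeSegmentSet
#' @export
readSegmentSet <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$kind, "segment_set")) {
    stop("not a SegmentSet container: ", path)
  }
  segmentSet(obj$data, obj$labels, obj$subject_ids, obj$sampling_rate)
}

#' Write / read an EEGRecord container
#'
#' @param x an [EEGRecord-class].
#' @param path file path.
#' @return `writeEEGRecord` returns `path` invisibly; `readEEGRecord`
#'   returns the [EEGRecord-class].
#' @export
writeEEGRecord <- function(x, path) {
  stopifnot(is(x, "EEGRecord"))
  saveRDS(list(data = x@data, channel_names = x@channelNames,
               sampling_rate = x@samplingRate, subject_id = x@subjectId,
               label = x@label, version = containerVersion,
               kind = "eeg_record"),
          path, version = 3)
  invisible(path)
}

#' @rdname writeEEGRecord
#' @export
readEEGRecord <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$kind, "eeg_record")) {
    stop("not an EEGRecord container: ", path)
  }
  eegRecord(obj$data, obj$sampling_rate, obj$channel_names, obj$subject_id,
            obj$label)
}

#' Save / load a model checkpoint
#'
#' A checkpoint bundles the full [ParameterStore-class] (weights, batch
#' norm state, configuration, initialization seed and scheme) in a single
#' versioned file; `loadCheckpoint(saveCheckpoint(s, p))` reproduces
#' forward passes bit-exactly.
#'
#' @param store a [ParameterStore-class].
#' @param path file path.
#' @return `saveCheckpoint` returns `path` invisibly; `loadCheckpoint`
#'   returns the [ParameterStore-class].
#' @export
saveCheckpoint <- function(store, path) {
  stopifnot(is(store, "ParameterStore"))
  saveRDS(list(weights = store@weights, state = store@state,
               config = store@config, seed = store@seed,
               scheme = store@scheme, version = containerVersion,
               kind = "checkpoint"),
          path, version = 3)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$kind, "checkpoint")) {
    stop("not a checkpoint container: ", path)
  }
  new("ParameterStore", weights = obj$weights, state = obj$state,
      config = obj$config, seed = obj$seed, scheme = obj$scheme)
}
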