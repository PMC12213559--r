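## Subject-aware train/test splitting.

#' Split a SegmentSet into train and test indices
#'
#' Two protocols:
#' \describe{
#'   \item{per_subject_segments}{for every subject, `trainFraction` of that
#'     subject's segments (floor) go to train and the rest to test.  Every
#'     subject contributes to both sets, so segment-level leakage across
#'     sets is possible by design.}
#'   \item{subject_wise}{`trainFraction` of the subjects (floor, stratified
#'     by class) go wholly to train, the rest wholly to test, so the
#'     subject-ID sets are provably disjoint.  This is the stricter,
#'     leakage-free protocol and the package default.}
#' }
#' Both are deterministic under `seed`.
#'
#' @param data a [SegmentSet-class].
#' @param mode "subject_wise" (default) or "per_subject_segments".
#' @param trainFraction fraction assigned to training (default 0.8).
#' @param seed integer seed.
#' @return a [SplitPlan-class].
#' @examples
#' spec <- syntheticSpec(nSubjectsPerClass = 5, segmentsPerSubject = 4,
#'                       nChannels = 2)
#' ds <- generateDataset(spec)
#' plan <- makeSplit(ds, "subject_wise", seed = 7)
#' plan
#' @export
makeSplit <- function(data, mode = c("subject_wise", "per_subject_segments"),
                      trainFraction = 0.8, seed = 1L) {
  stopifnot(is(data, "SegmentSet"))
  mode <- match.arg(mode)
  if (trainFraction <= 0 || trainFraction >= 1) {
    stop("trainFraction must lie strictly between 0 and 1")
  }
  subj <- data@subjectIds
  labs <- data@labels
  withSeed(seed, {
    if (mode == "per_subject_segments") {
      train <- integer(0)
      test <- integer(0)
      for (s in unique(subj)) {
        idx <- which(subj == s)
        idx <- idx[sample.int(length(idx))]
        nTrain <- floor(trainFraction * length(idx))
        if (nTrain == length(idx)) nTrain <- length(idx) - 1L
        if (nTrain < 1L) {
          stop(sprintf("subject %s has too few segments to split", s))
        }
        train <- c(train, idx[seq_len(nTrain)])
        test <- c(test, idx[-seq_len(nTrain)])
      }
    } else {
      train <- integer(0)
      test <- integer(0)
      for (cl in c(0L, 1L)) {
        subs <- unique(subj[labs == cl])
        if (length(subs) < 2L) {
          stop("subject_wise mode needs at least 2 subjects per class")
        }
        subs <- subs[sample.int(length(subs))]
        nTrain <- floor(trainFraction * length(subs))
        if (nTrain == length(subs)) nTrain <- length(subs) - 1L
        if (nTrain < 1L) nTrain <- 1L
        trainSubs <- subs[seq_len(nTrain)]
        train <- c(train, which(subj %in% trainSubs))
        test <- c(test, which(subj %in% setdiff(subs, trainSubs)))
      }
    }
    if (!length(test)) stop("split produced an empty test set")
    new("SplitPlan", mode = mode, trainFraction = trainFraction,
        seed = as.integer(seed), trainIndices = sort(as.integer(train)),
        testIndices = sort(as.integer(test)))
  })
}
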