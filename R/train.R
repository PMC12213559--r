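## Adam trainer with fully seeded initialization and data order.

#' Create a training configuration
#'
#' Defaults: Adam with decoupled weight decay (peak learning rate 1e-3,
#' decay coefficient 0.01), a cosine learning-rate schedule annealing to
#' zero over the epoch budget, minibatches of 32, 30 epochs,
#' cross-entropy loss, no early stopping.  On cohort-style EEG the
#' failure mode of long unregularized runs is *subject-level*
#' overfitting — the network keys on per-subject channel profiles — and
#' the decay pair (weight decay + annealed steps) is what keeps held-out
#' subject accuracy at its plateau through the end of the budget.
#'
#' @param epochs maximum passes over the training data.
#' @param batchSize minibatch size.
#' @param learningRate peak Adam step size (0 leaves parameters
#'   untouched).
#' @param lrSchedule "cosine" (default; anneal to 0 across `epochs`) or
#'   "constant".
#' @param weightDecay decoupled (AdamW-style) weight-decay coefficient.
#' @param optimizer optimizer label; "adam".
#' @param loss loss label; "cross_entropy".
#' @param seed seed for initialization, shuffling and (when early
#'   stopping is enabled) the validation hold-out.
#' @param earlyStopPatience epochs without improvement of the monitored
#'   quantity before stopping, or NA (default) to disable early stopping
#'   and its hold-out and train on everything for the full budget.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(epochs = 30L, batchSize = 32L, learningRate = 1e-3,
                        lrSchedule = c("cosine", "constant"),
                        weightDecay = 0.01, optimizer = "adam",
                        loss = "cross_entropy", seed = 1L,
                        earlyStopPatience = NA_integer_) {
  lrSchedule <- match.arg(lrSchedule)
  new("TrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate), lrSchedule = lrSchedule,
      weightDecay = as.numeric(weightDecay), optimizer = optimizer,
      loss = loss, seed = as.integer(seed),
      earlyStopPatience = as.integer(earlyStopPatience))
}

## learning rate for epoch e of E under the configured schedule
scheduledLr <- function(tc, epoch) {
  if (tc@lrSchedule == "cosine") {
    tc@learningRate * 0.5 * (1 + cos(pi * (epoch - 1) / tc@epochs))
  } else {
    tc@learningRate
  }
}

## recursive elementwise map over a nested list of numeric arrays
mapLeaves <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1]])) {
    out <- vector("list", length(args[[1]]))
    names(out) <- names(args[[1]])
    for (i in seq_along(out)) {
      out[[i]] <- do.call(mapLeaves, c(list(f), lapply(args, `[[`, i)))
    }
    out
  } else {
    do.call(f, args)
  }
}

zeroLike <- function(w) mapLeaves(function(a) a * 0, w)

adamUpdate <- function(w, g, m, v, t, lr, wd = 0, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  m <- mapLeaves(function(mm, gg) beta1 * mm + (1 - beta1) * gg, m, g)
  v <- mapLeaves(function(vv, gg) beta2 * vv + (1 - beta2) * gg^2, v, g)
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  w <- mapLeaves(function(ww, mm, vv) {
    ## decoupled weight decay (AdamW): shrink, then take the Adam step
    ww * (1 - lr * wd) - lr * (mm / corr1) / (sqrt(vv / corr2) + eps)
  }, w, m, v)
  list(w = w, m = m, v = v)
}

bnMomentum <- 0.1

applyBnUpdates <- function(state, bnStats) {
  if (is.null(bnStats)) return(state)
  for (nm in names(bnStats)) {
    state$embed[[nm]]$mean <- (1 - bnMomentum) * state$embed[[nm]]$mean +
      bnMomentum * bnStats[[nm]]$mean
    state$embed[[nm]]$var <- (1 - bnMomentum) * state$embed[[nm]]$var +
      bnMomentum * bnStats[[nm]]$var
  }
  state
}

## subject-wise validation hold-out: whole subjects (stratified by class)
## are moved to the validation side so the monitored accuracy estimates
## performance on unseen subjects
carveValidation <- function(data, fraction = 0.2, seed = 1L) {
  subj <- data@subjectIds
  labs <- data@labels
  withSeed(seed + 2L, {
    valSubs <- character(0)
    for (cl in unique(labs)) {
      subs <- unique(subj[labs == cl])
      if (length(subs) < 2L) next
      subs <- subs[sample.int(length(subs))]
      nVal <- max(1L, floor(fraction * length(subs)))
      valSubs <- c(valSubs, subs[seq_len(nVal)])
    }
    if (!length(valSubs)) return(list(train = data, val = NULL))
    keep <- !(subj %in% valSubs)
    list(train = data[which(keep)], val = data[which(!keep)])
  })
}

#' Train a DSCnet model
#'
#' Minimizes the softmax cross-entropy with Adam plus decoupled weight
#' decay under the configured learning-rate schedule.  By default
#' (patience NA) all supplied data are trained for the full epoch budget.
#' When `tc@earlyStopPatience` is set and no explicit validation set is
#' given, a subject-wise hold-out (20 percent of the training subjects,
#' stratified by class) is carved from `data`; validation accuracy is
#' monitored after every epoch, training stops after `earlyStopPatience`
#' epochs without improvement, and the weights of the best epoch are
#' restored.  Initialization, data order and the hold-out derive from
#' `tc@seed`, so the final parameters are fully deterministic; a
#' non-finite loss aborts with an explicit divergence error.
#'
#' @param data a [SegmentSet-class] of training segments (standardize it
#'   first; see [fitStandardization()]).
#' @param cfg a [ModelConfig-class]; `inChannels` must match the data.
#' @param tc a [TrainConfig-class].
#' @param validation optional explicit [SegmentSet-class] used as the
#'   monitored validation set instead of the carved hold-out.
#' @param store optional warm-start [ParameterStore-class]; by default
#'   parameters are initialized with `tc@seed`.
#' @param verbose log per-epoch progress.
#' @return list with `store` (the trained [ParameterStore-class]) and
#'   `history` (data.frame: epoch, loss, valAccuracy).
#' @export
trainDscnet <- function(data, cfg, tc = trainConfig(), validation = NULL,
                        store = NULL, verbose = FALSE) {
  stopifnot(is(data, "SegmentSet"), is(cfg, "ModelConfig"),
            is(tc, "TrainConfig"))
  validObject(tc)
  if (nSegments(data) < 1L) stop("training data are empty")
  if (is.null(store)) store <- initParameters(cfg, tc@seed)
  monitor <- !is.na(tc@earlyStopPatience)
  if (monitor && is.null(validation)) {
    parts <- carveValidation(data, 0.2, tc@seed)
    data <- parts$train
    validation <- parts$val
  }
  cube <- segmentsToCube(data@segments)
  yIdx <- data@labels + 1L
  N <- dim(cube)[3]
  w <- store@weights
  st <- store@state
  m <- zeroLike(w)
  v <- zeroLike(w)
  tStep <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        valAccuracy = numeric(0))
  best <- -Inf
  bestW <- w
  bestSt <- st
  stale <- 0L
  withSeed(tc@seed + 1L, {
    for (epoch in seq_len(tc@epochs)) {
      ord <- sample.int(N)
      epochLoss <- 0
      nBatches <- 0L
      for (from in seq(1L, N, by = tc@batchSize)) {
        idx <- ord[from:min(from + tc@batchSize - 1L, N)]
        lg <- modelLossGrad(w, st, cfg, cube[, , idx, drop = FALSE],
                            yIdx[idx])
        if (!is.finite(lg$loss)) {
          stop(sprintf("training diverged (non-finite loss at epoch %d)",
                       epoch))
        }
        tStep <- tStep + 1L
        upd <- adamUpdate(w, lg$grads, m, v, tStep, scheduledLr(tc, epoch),
                          tc@weightDecay)
        w <- upd$w; m <- upd$m; v <- upd$v
        st <- applyBnUpdates(st, lg$bnStats)
        epochLoss <- epochLoss + lg$loss
        nBatches <- nBatches + 1L
      }
      epochLoss <- epochLoss / nBatches
      valAcc <- NA_real_
      if (!is.null(validation)) {
        tmp <- store
        tmp@weights <- w; tmp@state <- st
        valAcc <- mean(predictLabels(tmp, validation) == validation@labels)
      }
      history[epoch, ] <- list(epoch, epochLoss, valAcc)
      dscnetLog("info", "epoch %d/%d loss %.4f%s", epoch, tc@epochs,
                epochLoss,
                if (is.na(valAcc)) "" else sprintf(" val acc %.3f", valAcc),
                verbose = verbose)
      ## monitored quantity: validation accuracy if available, else the
      ## (negated) training loss
      score <- if (!is.null(validation)) valAcc else -epochLoss
      if (score > best + 1e-9) {
        best <- score
        stale <- 0L
        if (monitor) { bestW <- w; bestSt <- st }
      } else {
        stale <- stale + 1L
      }
      if (monitor && stale >= tc@earlyStopPatience) break
    }
  })
  if (monitor) {
    store@weights <- bestW
    store@state <- bestSt
  } else {
    store@weights <- w
    store@state <- st
  }
  list(store = store, history = history)
}

#' Evaluate a trained model on a SegmentSet
#'
#' Deterministic forward pass (inference mode), argmax prediction with
#' ties broken toward the lower class index, and [computeMetrics()] on the
#' result.
#'
#' @param store a [ParameterStore-class].
#' @param data a [SegmentSet-class].
#' @param splitDescriptor free-text description stored in the report.
#' @param seed seed to record in the report (bookkeeping only).
#' @param aggregate "segment" scores each segment independently;
#'   "subject_vote" aggregates segment predictions per subject by majority
#'   vote (ties toward class 0) and scores subjects.
#' @return an [EvalReport-class].
#' @export
evaluateModel <- function(store, data, splitDescriptor = "",
                          seed = NA_integer_,
                          aggregate = c("segment", "subject_vote")) {
  aggregate <- match.arg(aggregate)
  pred <- predictLabels(store, data)
  truth <- data@labels
  if (aggregate == "subject_vote") {
    subj <- data@subjectIds
    us <- unique(subj)
    pred <- vapply(us, function(s) {
      as.integer(mean(pred[subj == s]) > 0.5)
    }, integer(1))
    truth <- vapply(us, function(s) truth[subj == s][1], integer(1))
  }
  computeMetrics(truth, pred, splitDescriptor = splitDescriptor, seed = seed)
}
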