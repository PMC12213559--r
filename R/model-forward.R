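## Whole-network forward/backward, the cross-entropy objective, and the
## exported block-level API used for verification against loop oracles.

networkF <- function(weights, state, cfg, x, training = FALSE) {
  caches <- list()
  h <- x
  if (cfg@useEmbedding) {
    e <- embedF(h, weights$embed, state$embed, training)
    h <- e$y
    caches$embed <- e$cache
  }
  if (cfg@useStage2) {
    caches$rounds <- vector("list", cfg@rounds)
    for (r in seq_len(cfg@rounds)) {
      rf <- roundF(h, weights$rounds[[r]], cfg)
      h <- rf$y
      caches$rounds[[r]] <- rf$cache
    }
  }
  cf <- clfF(h, weights$clf)
  caches$clf <- cf$cache
  list(scores = cf$y, caches = caches)
}

networkB <- function(caches, weights, cfg, ds) {
  g <- list()
  cb <- clfB(caches$clf, weights$clf, ds)
  dh <- cb$dx
  if (cfg@useStage2) {
    g$rounds <- vector("list", cfg@rounds)
    for (r in rev(seq_len(cfg@rounds))) {
      rb <- roundB(caches$rounds[[r]], weights$rounds[[r]], cfg, dh)
      dh <- rb$dx
      g$rounds[[r]] <- rb$g
    }
  }
  if (cfg@useEmbedding) {
    eb <- embedB(caches$embed, weights$embed, dh)
    dh <- eb$dx
    g$embed <- eb$g
  }
  g$clf <- cb$g
  ## reorder to mirror the weight structure exactly
  list(dx = dh, g = g[names(weights)])
}

## mean softmax cross-entropy; yIdx is the 1-based class index per column
softmaxCE <- function(scores, yIdx) {
  K <- nrow(scores); N <- ncol(scores)
  m <- apply(scores, 2, max)
  e <- exp(sweep(scores, 2, m, "-"))
  p <- sweep(e, 2, colSums(e), "/")
  picked <- p[cbind(yIdx, seq_len(N))]
  loss <- -mean(log(pmax(picked, .Machine$double.xmin)))
  dS <- p
  dS[cbind(yIdx, seq_len(N))] <- dS[cbind(yIdx, seq_len(N))] - 1
  list(loss = loss, dScores = dS / N, probs = p)
}

## loss + gradients + batch-norm statistics for one minibatch
modelLossGrad <- function(weights, state, cfg, x, yIdx) {
  f <- networkF(weights, state, cfg, x, training = TRUE)
  l <- softmaxCE(f$scores, yIdx)
  b <- networkB(f$caches, weights, cfg, l$dScores)
  bnStats <- NULL
  if (cfg@useEmbedding) {
    cc <- f$caches$embed
    bnStats <- list(
      bn1 = list(mean = as.numeric(cc$b1$mean), var = as.numeric(cc$b1$var)),
      bn2 = list(mean = as.numeric(cc$b2$mean), var = as.numeric(cc$b2$var)),
      bn3 = list(mean = as.numeric(cc$b3$mean), var = as.numeric(cc$b3$var)))
  }
  list(loss = l$loss, grads = b$g, bnStats = bnStats)
}

asFeatureCube <- function(x) {
  if (is(x, "SegmentSet")) return(segmentsToCube(x@segments))
  d <- dim(x)
  if (length(d) == 4L) return(segmentsToCube(x))
  if (length(d) == 3L) return(x)
  if (length(d) == 2L) return(array(x, dim = c(d, 1L)))
  stop("expected a SegmentSet or a (C x T x N) array")
}

#' Forward pass of the full network
#'
#' Runs embedding, all stage-2 rounds and the classifier, returning raw
#' class scores (one column per segment).  Deterministic given the
#' parameter store; inference mode uses the batch-normalization running
#' statistics.
#'
#' @param store a [ParameterStore-class].
#' @param x a [SegmentSet-class], an (N x C x 1 x T) array or a
#'   (C x T x N) array.
#' @param training use batch statistics in the normalization layers
#'   (training mode) instead of running statistics.
#' @return numeric matrix `nClasses x N` of class scores.
#' @seealso [predictLabels()], [trainDscnet()]
#' @export
dscnetForward <- function(store, x, training = FALSE) {
  stopifnot(is(store, "ParameterStore"))
  cube <- asFeatureCube(x)
  cfg <- store@config
  if (dim(cube)[1] != cfg@inChannels) {
    stop(sprintf("input has %d channels but the model expects %d",
                 dim(cube)[1], cfg@inChannels))
  }
  if (cfg@useStage2 &&
      dim(cube)[2] < cfg@maxpoolSize^cfg@rounds) {
    stop("time length too short for the configured rounds of pooling")
  }
  networkF(store@weights, store@state, cfg, cube, training = training)$scores
}

#' Predict class labels
#'
#' Argmax over [dscnetForward()] scores, evaluated in chunks; score ties
#' break toward the lower class index.
#'
#' @param store a [ParameterStore-class].
#' @param x input as in [dscnetForward()].
#' @param chunkSize number of segments per forward chunk.
#' @return integer vector of 0-based class labels.
#' @export
predictLabels <- function(store, x, chunkSize = 256L) {
  cube <- asFeatureCube(x)
  N <- dim(cube)[3]
  out <- integer(N)
  for (from in seq(1L, N, by = chunkSize)) {
    to <- min(from + chunkSize - 1L, N)
    sc <- dscnetForward(store, cube[, , from:to, drop = FALSE])
    out[from:to] <- apply(sc, 2, which.max) - 1L
  }
  out
}

## ---------------------------------------------------- exported block API

blockWeights <- function(store, what, round = 1L) {
  w <- store@weights
  switch(what,
    embed = w$embed,
    round = w$rounds[[round]],
    clf = w$clf)
}

#' Individual network blocks
#'
#' Forward-only access to each block of the network, mainly for
#' verification and inspection.  All functions accept a feature cube in
#' any of the layouts understood by [dscnetForward()] and return the
#' block's output as a (C x T x N) array (a score matrix for
#' `classifyBlock`).
#'
#' @param x input feature map.
#' @param store a [ParameterStore-class].
#' @param round stage-2 round index (weights are independent per round).
#' @param training batch-norm mode for `embedBlock`.
#' @return the block output.
#' @name dscnet-blocks
NULL

#' @describeIn dscnet-blocks stage-1 hybrid embedding: three 1 x 3
#'   convolutions with batch norm + GELU, a 1 x 1 residual skip, and
#'   concatenation with a 1 x 1 projection of the input
#'   (`2 * embedWidth` output channels).
#' @export
embedBlock <- function(x, store, training = FALSE) {
  embedF(asFeatureCube(x), store@weights$embed, store@state$embed,
         training)$y
}

#' @describeIn dscnet-blocks depthwise 1 x 3 convolution followed by 1 x 1
#'   pointwise mixing (or a dense 1 x 3 convolution for `convType = "sc"`).
#' @export
depthwiseSeparableConv <- function(x, store, round = 1L) {
  convStepF(asFeatureCube(x), store@weights$rounds[[round]],
            store@config)$y
}

#' @describeIn dscnet-blocks directional adaptive feature modulation:
#'   channel split, per-scale depthwise 1 x 3 convolutions with temporal
#'   max-pool / nearest-neighbour upsampling, 1 x 1 fusion and GELU-gated
#'   elementwise modulation of the input.
#' @export
dafmBlock <- function(x, store, round = 1L) {
  dafmF(asFeatureCube(x), store@weights$rounds[[round]]$dafm,
        store@config)$y
}

#' @describeIn dscnet-blocks CoT attention: static context from a grouped
#'   1 x k convolution, attention logits from two stacked 1 x 1
#'   convolutions on \[K1, Q\], softmax-weighted aggregation of V over each
#'   position's k-neighbourhood, fused as K1 + K2.
#' @export
cotAttention <- function(x, store, round = 1L) {
  cotF(asFeatureCube(x), store@weights$rounds[[round]]$cot,
       store@config)$y
}

#' @describeIn dscnet-blocks one full stage-2 round:
#'   `maxpool(dafm(h) + cot(h))` with `h` the depthwise-separable features.
#' @export
stage2Round <- function(x, store, round = 1L) {
  roundF(asFeatureCube(x), store@weights$rounds[[round]], store@config)$y
}

#' @describeIn dscnet-blocks classifier: global average pooling over time,
#'   a hidden 1 x 1 layer with GELU, and a 1 x 1 output layer.
#' @export
classifyBlock <- function(x, store) {
  clfF(asFeatureCube(x), store@weights$clf)$y
}

## ------------------------------------------------- gradient verification

flattenWeights <- function(w) unlist(w, use.names = FALSE)

unflattenWeights <- function(vec, skel) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- vec[pos + seq_len(n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  walk(skel)
}

#' Finite-difference gradient check
#'
#' Compares the analytic gradient of the training loss against central
#' finite differences on a random subset of parameter coordinates, in
#' double precision and with batch-mode normalization so the loss is a
#' deterministic function of the weights.  The loss surface has kinks
#' (max pooling, attention argmax margins); a secant at the nominal step
#' occasionally straddles one, so any coordinate that misses the
#' tolerance is re-estimated at `step / 10` — the secant of a correct
#' analytic gradient converges under refinement, while a genuine backward
#' error does not.
#'
#' @param store a [ParameterStore-class].
#' @param x input feature map (small; e.g. 4 channels x 32 samples).
#' @param y integer labels (0-based), length N.
#' @param nCoords number of randomly chosen coordinates to test.
#' @param step finite-difference step size.
#' @param seed seed for the coordinate draw.
#' @return named list: `maxRelError` and a data.frame of per-coordinate
#'   results.
#' @export
gradientCheck <- function(store, x, y, nCoords = 50L, step = 1e-4,
                          seed = 1L) {
  cube <- asFeatureCube(x)
  cfg <- store@config
  yIdx <- as.integer(y) + 1L
  w <- store@weights
  analytic <- modelLossGrad(w, store@state, cfg, cube, yIdx)$grads
  flatW <- flattenWeights(w)
  flatG <- flattenWeights(analytic)
  coords <- withSeed(seed, sample.int(length(flatW), min(nCoords,
                                                         length(flatW))))
  lossAt <- function(v) {
    ww <- unflattenWeights(v, w)
    f <- networkF(ww, store@state, cfg, cube, training = TRUE)
    softmaxCE(f$scores, yIdx)$loss
  }
  fd <- function(i, h) {
    vp <- flatW; vp[i] <- vp[i] + h
    vm <- flatW; vm[i] <- vm[i] - h
    (lossAt(vp) - lossAt(vm)) / (2 * h)
  }
  num <- vapply(coords, fd, numeric(1), h = step)
  ana <- flatG[coords]
  ## relative error with an absolute floor: below the floor the finite
  ## difference itself is dominated by truncation error
  relErr <- function(num) {
    abs(num - ana) / pmax(abs(num), abs(ana), 1e-4)
  }
  rel <- relErr(num)
  refine <- which(rel > 1e-4)
  if (length(refine)) {
    num[refine] <- vapply(coords[refine], fd, numeric(1), h = step / 10)
    rel <- relErr(num)
  }
  list(maxRelError = max(rel),
       table = data.frame(coord = coords, analytic = ana, numeric = num,
                          relError = rel))
}
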