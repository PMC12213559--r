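## Architecture configuration, parameter initialization and bookkeeping.

#' Create a DSCnet model configuration
#'
#' Canonical architecture: a stage-1 hybrid embedding (three 1 x 3
#' convolutions with batch normalization and GELU, a 1 x 1 residual skip,
#' concatenated with a 1 x 1 projection of the raw input), two stage-2
#' rounds of depthwise-separable convolution refined in parallel by DAFM
#' (2 scale levels) and CoT attention and closed by temporal max pooling,
#' and a global-average-pooling classifier with one hidden 1 x 1 layer.
#'
#' @param inChannels input channel count C (e.g. 8 synthetic, 32 or 61 for
#'   the real montages).
#' @param embedWidth stage-1 per-branch width; the hybrid representation
#'   has `2 * embedWidth` channels.
#' @param stage2Width stage-2 channel width; must be divisible by
#'   `nLevels` (when DAFM is on) and by `cotGroups` (when CoT is on).
#' @param nLevels DAFM scale divisions (2 canonical; 4 is the ablation
#'   variant).
#' @param dafmPool DAFM temporal pooling base; level j pools by
#'   `dafmPool^j` (capped at the time length).
#' @param cotKernel odd temporal kernel/neighbourhood size k of CoT.
#' @param cotGroups groups of the CoT static-context convolution.
#' @param rounds stage-2 rounds (1-3 in the ablation grid).
#' @param maxpoolSize temporal pooling factor closing each round.
#' @param classifierHidden classifier hidden width.
#' @param nClasses output classes.
#' @param activation activation label; "gelu".
#' @param useEmbedding,convType,useDafm,useCot,useStage2 ablation toggles,
#'   see [ModelConfig-class].
#' @return a validated [ModelConfig-class].
#' @examples
#' cfg <- dscnetConfig(inChannels = 8)
#' cfg
#' countParameters(cfg)
#' @export
dscnetConfig <- function(inChannels, embedWidth = 16L, stage2Width = 32L,
                         nLevels = 2L, dafmPool = 2L, cotKernel = 3L,
                         cotGroups = 4L, rounds = 2L, maxpoolSize = 2L,
                         classifierHidden = 64L, nClasses = 2L,
                         activation = "gelu", useEmbedding = TRUE,
                         convType = c("dsc", "sc"), useDafm = TRUE,
                         useCot = TRUE, useStage2 = TRUE) {
  convType <- match.arg(convType)
  new("ModelConfig",
      inChannels = as.integer(inChannels),
      embedWidth = as.integer(embedWidth),
      stage2Width = as.integer(stage2Width),
      nLevels = as.integer(nLevels),
      dafmPool = as.integer(dafmPool),
      cotKernel = as.integer(cotKernel),
      cotGroups = as.integer(cotGroups),
      rounds = as.integer(rounds),
      maxpoolSize = as.integer(maxpoolSize),
      classifierHidden = as.integer(classifierHidden),
      nClasses = as.integer(nClasses),
      activation = activation,
      useEmbedding = isTRUE(useEmbedding),
      convType = convType,
      useDafm = isTRUE(useDafm),
      useCot = isTRUE(useCot),
      useStage2 = isTRUE(useStage2))
}

## Fan-in normal initialization for a conv kernel array (Cout x Cin_g x k);
## biases start at zero.  `gain` < 1 is used for the modulation layers
## (DAFM fusion, CoT attention logits): their outputs enter multiplicative
## or softmax paths, and a small initial scale keeps those paths
## near-linear so activations stay O(1) through stacked rounds.
kaimingConv <- function(cOut, cInG, k, gain = 1) {
  sd <- gain * sqrt(1 / (cInG * k))
  list(w = array(stats::rnorm(cOut * cInG * k, 0, sd), dim = c(cOut, cInG, k)),
       b = numeric(cOut))
}

kaimingDense <- function(nOut, nIn, gain = 1) {
  list(w = matrix(stats::rnorm(nOut * nIn, 0, gain * sqrt(1 / nIn)), nOut, nIn),
       b = numeric(nOut))
}

bnParams <- function(c) list(gamma = rep(1, c), beta = numeric(c))
bnState <- function(c) list(mean = numeric(c), var = rep(1, c))

## channel count entering stage 2 / the classifier
stage2InChannels <- function(cfg) {
  if (cfg@useEmbedding) 2L * cfg@embedWidth else cfg@inChannels
}

classifierInChannels <- function(cfg) {
  if (cfg@useStage2) cfg@stage2Width else stage2InChannels(cfg)
}

#' Initialize model parameters
#'
#' Draws every convolution kernel with fan-in normal initialization
#' (sd `1/sqrt(fan_in)`) and zero biases, under a fixed seed recorded in
#' the returned store.  The DAFM fusion and CoT attention-logit kernels are
#' drawn 10x smaller so the multiplicative/softmax paths start near-linear
#' and activations stay O(1) through stacked rounds.  Batch-normalization
#' scale/shift start at (1, 0) and the running statistics at (0, 1).  Each
#' stage-2 round has independent weights.
#'
#' @param cfg a [ModelConfig-class].
#' @param seed integer initialization seed.
#' @return a [ParameterStore-class].
#' @export
initParameters <- function(cfg, seed = 1L) {
  stopifnot(is(cfg, "ModelConfig"))
  validObject(cfg)
  withSeed(seed, {
    w <- list()
    st <- list()
    if (cfg@useEmbedding) {
      E <- cfg@embedWidth
      C <- cfg@inChannels
      w$embed <- list(
        conv1 = kaimingConv(E, C, 3L), bn1 = bnParams(E),
        conv2 = kaimingConv(E, E, 3L), bn2 = bnParams(E),
        conv3 = kaimingConv(E, E, 3L), bn3 = bnParams(E),
        skip = kaimingConv(E, C, 1L),
        proj = kaimingConv(E, C, 1L)
      )
      st$embed <- list(bn1 = bnState(E), bn2 = bnState(E), bn3 = bnState(E))
    }
    if (cfg@useStage2) {
      W <- cfg@stage2Width
      cin <- stage2InChannels(cfg)
      w$rounds <- vector("list", cfg@rounds)
      for (r in seq_len(cfg@rounds)) {
        rw <- list()
        if (cfg@convType == "dsc") {
          rw$dw <- kaimingConv(cin, 1L, 3L)          # depthwise, groups = cin
          rw$pw <- kaimingConv(W, cin, 1L)           # pointwise mixing
        } else {
          rw$sc <- kaimingConv(W, cin, 3L)           # standard dense conv
        }
        if (cfg@useDafm) {
          cw <- W %/% cfg@nLevels
          dw <- lapply(seq_len(cfg@nLevels), function(j) {
            kaimingConv(cw, 1L, 3L)
          })
          names(dw) <- paste0("level", seq_len(cfg@nLevels))
          rw$dafm <- list(
            dw = dw,
            fuse = kaimingConv(W, W, 1L, gain = 0.1)
          )
        }
        if (cfg@useCot) {
          k <- cfg@cotKernel
          rw$cot <- list(
            k1 = kaimingConv(W, W %/% cfg@cotGroups, k),
            attn1 = kaimingConv(W, 2L * W, 1L),
            attn2 = kaimingConv(W * k, W, 1L, gain = 0.1),
            v = kaimingConv(W, W, 1L)
          )
        }
        w$rounds[[r]] <- rw
        cin <- W
      }
    }
    cClf <- classifierInChannels(cfg)
    w$clf <- list(fc1 = kaimingDense(cfg@classifierHidden, cClf),
                  fc2 = kaimingDense(cfg@nClasses, cfg@classifierHidden))
    new("ParameterStore", weights = w, state = st, config = cfg,
        seed = as.integer(seed), scheme = "fan_in_scaled")
  })
}

#' Count learnable parameters
#'
#' Total number of learnable scalars (kernel weights and biases; the
#' batch-norm running statistics are excluded).
#'
#' @param x a [ModelConfig-class] or [ParameterStore-class].
#' @return integer count.
#' @export
countParameters <- function(x) {
  w <- if (is(x, "ParameterStore")) x@weights else initParameters(x, 0L)@weights
  sum(rapply(w, length, how = "unlist"))
}

#' Print a layer table for a configuration
#'
#' One row per layer with its kernel shape and parameter count, plus the
#' total.
#'
#' @param cfg a [ModelConfig-class].
#' @param quiet return the table without printing.
#' @return (invisibly) a data.frame with columns stage, layer, shape,
#'   params.
#' @export
modelSummary <- function(cfg, quiet = FALSE) {
  store <- initParameters(cfg, 0L)
  rows <- list()
  addConv <- function(stage, name, p) {
    d <- dim(p$w)
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, layer = name,
      shape = if (length(d) == 3L)
        sprintf("%d x %d x %d (+%d bias)", d[1], d[2], d[3], length(p$b))
      else sprintf("%d x %d (+%d bias)", d[1], d[2], length(p$b)),
      params = length(p$w) + length(p$b))
  }
  addBn <- function(stage, name, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, layer = name,
      shape = sprintf("gamma/beta x %d", length(p$gamma)),
      params = 2L * length(p$gamma))
  }
  walk <- function(stage, prefix, x) {
    for (nm in names(x)) {
      p <- x[[nm]]
      full <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
      if (is.list(p) && !is.null(p$w)) addConv(stage, full, p)
      else if (is.list(p) && !is.null(p$gamma)) addBn(stage, full, p)
      else if (is.list(p)) walk(stage, full, p)
    }
  }
  if (!is.null(store@weights$embed)) walk("1:embed", "", list(embed = store@weights$embed))
  if (!is.null(store@weights$rounds)) {
    for (r in seq_along(store@weights$rounds)) {
      walk(sprintf("2:round%d", r), sprintf("round%d", r),
           store@weights$rounds[[r]])
    }
  }
  walk("3:classifier", "", list(clf = store@weights$clf))
  tab <- do.call(rbind, rows)
  if (!quiet) {
    show(cfg)
    print(tab, row.names = FALSE)
    cat(sprintf("total learnable parameters: %d\n", sum(tab$params)))
  }
  invisible(tab)
}
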