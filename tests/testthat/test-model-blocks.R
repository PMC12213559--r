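## Block-level contracts: loop-oracle agreement, constructed-weight
## identities, shape preservation, parameter counting, checkpoints.

test_that("depthwise-separable conv matches the loop oracle and shapes", {
  cfg <- smallConfig()
  for (i in 1:10) {
    set.seed(100 + i)
    store <- randomizeWeights(initParameters(cfg, 1L), 100 + i)
    x <- randomCube(8, 8, 2)
    expect_lt(max(abs(depthwiseSeparableConv(x, store, round = 2) -
                        oracleDsc(x, store@weights$rounds[[2]]))), 1e-5)
  }
  big <- initParameters(dscnetConfig(8, embedWidth = 4, stage2Width = 16), 1L)
  expect_equal(dim(depthwiseSeparableConv(randomCube(8, 64, 1), big)),
               c(16L, 64L, 1L))
})

test_that("delta depthwise kernel + identity pointwise is the identity", {
  cfg <- smallConfig()
  store <- initParameters(cfg, 1L)
  rw <- store@weights$rounds[[1]]
  rw$dw$w[] <- 0; rw$dw$w[, 1, 2] <- 1; rw$dw$b[] <- 0
  rw$pw$w[] <- 0
  for (c in 1:8) rw$pw$w[c, c, 1] <- 1
  rw$pw$b[] <- 0
  store@weights$rounds[[1]] <- rw
  x <- randomCube(8, 16, 3)
  expect_equal(depthwiseSeparableConv(x, store), x)
})

test_that("DAFM matches the equation-by-equation loop oracle", {
  cfg <- smallConfig()           # n_levels = 2 on 8 channels
  for (i in 1:10) {
    set.seed(200 + i)
    store <- randomizeWeights(initParameters(cfg, 1L), 200 + i)
    x <- randomCube(8, 8, 2)
    expect_lt(max(abs(dafmBlock(x, store) -
                        oracleDafm(x, store@weights$rounds[[1]]$dafm, cfg))),
              1e-5)
  }
})

test_that("DAFM gates to zero on zero input and preserves shape at n_levels 4", {
  cfg4 <- smallConfig(nLevels = 4L)
  store <- randomizeWeights(initParameters(cfg4, 1L), 7)
  z <- array(0, c(8, 16, 2))
  expect_equal(dafmBlock(z, store), z)      # modulation multiplies by x
  x <- randomCube(8, 16, 2)
  out <- dafmBlock(x, store)
  expect_equal(dim(out), dim(x))            # 4 branches, factors 1/2/4/8
  expect_lt(max(abs(out - oracleDafm(x, store@weights$rounds[[1]]$dafm,
                                     cfg4))), 1e-5)
  ## sign pattern equals independently computed GELU gate times input
  gate <- oracleGelu(dscnet:::convF(
    local({
      w <- store@weights$rounds[[1]]$dafm
      xc <- array(0, dim(x))
      cw <- 8L %/% 4L
      for (j in 1:4) {
        rng <- (j - 1L) * cw + seq_len(cw)
        fj <- min(2L^(j - 1L), 16L)
        xj <- x[rng, , , drop = FALSE]
        if (fj > 1L) {
          xc[rng, , ] <- oracleUpsampleNN(
            oracleConv1d(oracleMaxpool(xj, fj), w$dw[[j]]$w, w$dw[[j]]$b,
                         cw), fj, 16L)
        } else {
          xc[rng, , ] <- oracleConv1d(xj, w$dw[[j]]$w, w$dw[[j]]$b, cw)
        }
      }
      xc
    }), store@weights$rounds[[1]]$dafm$fuse))
  keep <- abs(out) > 1e-12     # away from floating-point sign ambiguity
  expect_equal(sign(out)[keep], sign(gate * x)[keep])
})

test_that("odd time lengths survive DAFM pool/upsample round trips", {
  cfg <- smallConfig()
  store <- randomizeWeights(initParameters(cfg, 1L), 3)
  for (Tn in c(5L, 7L, 9L, 15L)) {
    x <- randomCube(8, Tn, 2)
    out <- dafmBlock(x, store)
    expect_equal(dim(out), dim(x))
    expect_lt(max(abs(out - oracleDafm(x, store@weights$rounds[[1]]$dafm,
                                       cfg))), 1e-5)
  }
})

test_that("CoT attention matches the loop oracle and propagates zeros", {
  cfg <- smallConfig()
  for (i in 1:10) {
    set.seed(300 + i)
    store <- randomizeWeights(initParameters(cfg, 1L), 300 + i)
    x <- randomCube(8, 8, 2)
    expect_lt(max(abs(cotAttention(x, store) -
                        oracleCot(x, store@weights$rounds[[1]]$cot, cfg))),
              1e-5)
  }
  ## zero input with zero biases -> zero output
  store <- randomizeWeights(initParameters(cfg, 1L), 4)
  store@weights$rounds[[1]]$cot <- dscnet:::mapLeaves(function(a) {
    if (is.null(dim(a))) a * 0 else a
  }, store@weights$rounds[[1]]$cot)
  z <- array(0, c(8, 16, 2))
  expect_equal(cotAttention(z, store), z)
  ## shape contract
  expect_equal(dim(cotAttention(randomCube(8, 64, 1), store)),
               c(8L, 64L, 1L))
})

test_that("embedding: shape contract, zero propagation, constructed skip", {
  cfg <- dscnetConfig(4, embedWidth = 8)
  store <- initParameters(cfg, 1L)
  expect_equal(dim(embedBlock(randomCube(4, 32, 2), store)),
               c(16L, 32L, 2L))
  ## all-zero input with zero biases -> all-zero output (GELU(0) = 0,
  ## batch-norm running stats at (0, 1))
  z <- array(0, c(4, 32, 2))
  expect_equal(max(abs(embedBlock(z, store))), 0)
  ## zeroed main path + identity skip and projection -> both hybrid halves
  ## equal the input
  cfgI <- dscnetConfig(4, embedWidth = 4)
  si <- initParameters(cfgI, 1L)
  w <- si@weights$embed
  for (nm in c("conv1", "conv2", "conv3")) { w[[nm]]$w[] <- 0; w[[nm]]$b[] <- 0 }
  w$skip$w[] <- 0; for (c in 1:4) w$skip$w[c, c, 1] <- 1
  w$proj$w[] <- 0; for (c in 1:4) w$proj$w[c, c, 1] <- 1
  si@weights$embed <- w
  x <- randomCube(4, 16, 2)
  h <- embedBlock(x, si)
  expect_equal(h[1:4, , ], x[, , ])
  expect_equal(h[5:8, , ], x[, , ])
})

test_that("stage-2 round: pooling arithmetic and branch ablation symmetry", {
  cfg <- smallConfig()
  store <- randomizeWeights(initParameters(cfg, 1L), 11)
  x <- randomCube(8, 64, 2)
  out <- stage2Round(x, store)
  expect_equal(dim(out), c(8L, 32L, 2L))     # T halved, width preserved
  ## zeroing the DAFM fusion layer silences that branch: the round equals
  ## maxpool(cot branch alone)
  silenced <- store
  silenced@weights$rounds[[1]]$dafm$fuse$w[] <- 0
  silenced@weights$rounds[[1]]$dafm$fuse$b[] <- 0
  cotOnly <- oracleMaxpool(
    oracleCot(oracleDsc(x, store@weights$rounds[[1]]),
              store@weights$rounds[[1]]$cot, cfg), 2L)
  expect_lt(max(abs(stage2Round(x, silenced) - cotOnly)), 1e-5)
  ## constant input with delta/identity conv weights pools to the constant
  ident <- initParameters(cfg, 1L)
  rw <- ident@weights$rounds[[1]]
  rw$dw$w[] <- 0; rw$dw$w[, 1, 2] <- 1; rw$dw$b[] <- 0
  rw$pw$w[] <- 0; for (c in 1:8) rw$pw$w[c, c, 1] <- 1; rw$pw$b[] <- 0
  ident@weights$rounds[[1]] <- rw
  const <- array(2, c(8, 16, 1))
  h <- depthwiseSeparableConv(const, ident)
  expect_equal(h, const)
  expect_equal(dscnet:::maxpoolForwardCpp(const, 2L)$y, array(2, c(8, 8, 1)))
})

test_that("classifier matches a hand linear-algebra oracle", {
  cfg <- smallConfig()
  for (i in 1:10) {
    set.seed(400 + i)
    store <- randomizeWeights(initParameters(cfg, 1L), 400 + i)
    x <- randomCube(8, 12, 3)
    expect_lt(max(abs(classifyBlock(x, store) -
                        oracleClassify(x, store@weights$clf))), 1e-5)
  }
  ## constant feature map -> GAP returns the constant per channel
  store <- initParameters(cfg, 1L)
  const <- array(3.5, c(8, 10, 2))
  gap <- dscnet:::clfF(const, store@weights$clf)$cache$gap
  expect_equal(gap, matrix(3.5, 8, 2))
  ## zero weights, bias-only final layer -> scores equal the bias
  bias <- store
  bias@weights$clf$fc2$w[] <- 0
  bias@weights$clf$fc2$b <- c(-1, 2)
  sc <- classifyBlock(randomCube(8, 10, 4), bias)
  expect_equal(sc, matrix(c(-1, 2), 2, 4))
})

test_that("parameter counts match a closed-form shape walk", {
  ## a single 1x1 convolution 4 -> 2 with bias: 4*2 + 2 = 10
  p <- dscnet:::kaimingConv(2L, 4L, 1L)
  expect_equal(length(p$w) + length(p$b), 10L)
  ## depthwise 1x3 on 4 channels + pointwise 4 -> 8: (4*3+4)+(4*8+8) = 56
  dw <- dscnet:::kaimingConv(4L, 1L, 3L)
  pw <- dscnet:::kaimingConv(8L, 4L, 1L)
  expect_equal(length(dw$w) + length(dw$b) + length(pw$w) + length(pw$b),
               56L)
  ## full default architecture vs an independent closed-form sum
  shapeWalk <- function(cfg) {
    E <- cfg@embedWidth; C <- cfg@inChannels; W <- cfg@stage2Width
    k <- cfg@cotKernel; g <- cfg@cotGroups; L <- cfg@nLevels
    total <- 0
    if (cfg@useEmbedding) {
      total <- total + (E * C * 3 + E) + 2 * (E * E * 3 + E) + 3 * 2 * E +
        2 * (E * C + E)
    }
    cin <- if (cfg@useEmbedding) 2 * E else C
    for (r in seq_len(cfg@rounds)) {
      if (cfg@convType == "dsc") {
        total <- total + (cin * 3 + cin) + (W * cin + W)
      } else {
        total <- total + (W * cin * 3 + W)
      }
      if (cfg@useDafm) total <- total + L * ((W / L) * 3 + W / L) + W * W + W
      if (cfg@useCot) {
        total <- total + (W * (W / g) * k + W) + (W * 2 * W + W) +
          (W * k * W + W * k) + (W * W + W)
      }
      cin <- W
    }
    total + (cfg@classifierHidden * W + cfg@classifierHidden) +
      (cfg@nClasses * cfg@classifierHidden + cfg@nClasses)
  }
  for (cfg in list(dscnetConfig(32), dscnetConfig(8), smallConfig(),
                   dscnetConfig(8, convType = "sc"),
                   dscnetConfig(8, useDafm = FALSE, rounds = 3L))) {
    expect_equal(countParameters(cfg), shapeWalk(cfg))
  }
  tab <- modelSummary(dscnetConfig(8), quiet = TRUE)
  expect_equal(sum(tab$params), countParameters(dscnetConfig(8)))
})

test_that("checkpoints round-trip bit-exactly", {
  cfg <- smallConfig()
  store <- initParameters(cfg, 5L)
  x <- randomCube(4, 32, 2)
  path <- tempfile(fileext = ".dscnet")
  saveCheckpoint(store, path)
  back <- loadCheckpoint(path)
  expect_identical(back@weights, store@weights)
  expect_identical(dscnetForward(back, x), dscnetForward(store, x))
  expect_equal(back@seed, 5L)
  unlink(path)
})
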