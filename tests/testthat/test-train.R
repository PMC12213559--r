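## Trainer behaviour: zero step, loss descent, determinism, evaluation.

test_that("learning rate 0 leaves parameters untouched", {
  ds <- tinySegmentSet(2, 3, 4, 32)
  cfg <- smallConfig()
  fit <- trainDscnet(ds, cfg, trainConfig(epochs = 1, learningRate = 0,
                                          seed = 4))
  init <- initParameters(cfg, 4L)
  expect_identical(fit$store@weights, init@weights)
})

test_that("loss decreases on separable data (full-batch descent)", {
  ## classifier-only model on strongly separable band-power features
  ds <- generateDataset(syntheticSpec(
    nSubjectsPerClass = 4, segmentsPerSubject = 5, nChannels = 4,
    segmentLength = 64, powerRatio = 8, seed = 13))
  stats <- fitStandardization(ds)
  ds <- standardize(ds, stats)
  cfg <- dscnetConfig(4, useEmbedding = FALSE, useStage2 = FALSE,
                      classifierHidden = 8)
  fit <- trainDscnet(ds, cfg,
                     trainConfig(epochs = 10, batchSize = nSegments(ds),
                                 seed = 2, weightDecay = 0,
                                 earlyStopPatience = NA))
  expect_equal(nrow(fit$history), 10L)
  expect_true(all(diff(fit$history$loss) < 0))
})

test_that("training is deterministic under fixed seeds", {
  ds <- tinySegmentSet(2, 4, 4, 32, seed = 6)
  cfg <- smallConfig()
  tc <- trainConfig(epochs = 2, seed = 9)
  f1 <- trainDscnet(ds, cfg, tc)
  f2 <- trainDscnet(ds, cfg, tc)
  expect_identical(f1$store@weights, f2$store@weights)
  expect_identical(f1$store@state, f2$store@state)
  expect_identical(f1$history$loss, f2$history$loss)
})

test_that("divergence is reported explicitly", {
  ds <- tinySegmentSet(2, 3, 4, 32)
  cfg <- smallConfig()
  broken <- initParameters(cfg, 1L)
  broken@weights$clf$fc2$w[1, 1] <- Inf
  expect_error(trainDscnet(ds, cfg, trainConfig(epochs = 1),
                           store = broken),
               "diverged")
})

test_that("evaluation is deterministic and composes with computeMetrics", {
  ds <- tinySegmentSet(2, 4, 4, 32, seed = 5)
  cfg <- smallConfig()
  store <- initParameters(cfg, 1L)
  r1 <- evaluateModel(store, ds)
  r2 <- evaluateModel(store, ds)
  expect_identical(r1@perClass, r2@perClass)
  ## metrics equal computeMetrics applied to externally collected preds
  preds <- predictLabels(store, ds)
  ref <- computeMetrics(labels(ds), preds)
  expect_equal(accuracy(r1), accuracy(ref))
  expect_equal(r1@perClass, ref@perClass)
})

test_that("bias-only models predict the favoured class everywhere", {
  ds <- tinySegmentSet(3, 4, 4, 32, seed = 7)
  cfg <- smallConfig()
  store <- initParameters(cfg, 1L)
  store@weights$clf$fc2$w[] <- 0
  store@weights$clf$fc2$b <- c(0, 5)
  rep <- evaluateModel(store, ds)
  expect_equal(accuracy(rep), mean(labels(ds) == 1L))
  ## subject-level majority vote agrees for a constant predictor
  repSub <- evaluateModel(store, ds, aggregate = "subject_vote")
  expect_equal(accuracy(repSub), 0.5)
})

test_that("validation history and early stopping hooks work", {
  ds <- tinySegmentSet(2, 4, 4, 32, seed = 3)
  cfg <- smallConfig()
  fit <- trainDscnet(ds, cfg, trainConfig(epochs = 3, seed = 1),
                     validation = ds)
  expect_true(all(is.finite(fit$history$valAccuracy)))
  early <- trainDscnet(ds, cfg,
                       trainConfig(epochs = 50, learningRate = 0, seed = 1,
                                   earlyStopPatience = 2L))
  expect_lt(nrow(early$history), 50L)   # flat loss triggers the patience
})
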