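## Split hygiene and metric identities.

test_that("per-subject split assigns 80/20 of each subject's segments", {
  ds <- tinySegmentSet(nSub = 3, nSeg = 10)
  plan <- makeSplit(ds, "per_subject_segments", seed = 1)
  expect_equal(length(trainIndices(plan)), 6L * 8L)
  expect_equal(length(testIndices(plan)), 6L * 2L)
  ## indices disjoint and jointly covering
  expect_equal(sort(c(trainIndices(plan), testIndices(plan))),
               seq_len(nSegments(ds)))
  ## per subject exactly 8/2
  subj <- subjectIds(ds)
  for (s in unique(subj)) {
    expect_equal(sum(subj[trainIndices(plan)] == s), 8L)
    expect_equal(sum(subj[testIndices(plan)] == s), 2L)
  }
})

test_that("subject-wise split keeps subject sets disjoint and stratified", {
  ds <- tinySegmentSet(nSub = 5, nSeg = 4)
  plan <- makeSplit(ds, "subject_wise", seed = 3)
  subjTrain <- unique(subjectIds(ds)[trainIndices(plan)])
  subjTest <- unique(subjectIds(ds)[testIndices(plan)])
  expect_length(intersect(subjTrain, subjTest), 0L)
  ## 5 subjects/class -> 4 + 4 train, 1 + 1 test
  labTrain <- labels(ds)[match(subjTrain, subjectIds(ds))]
  labTest <- labels(ds)[match(subjTest, subjectIds(ds))]
  expect_equal(as.numeric(table(labTrain)), c(4, 4))
  expect_equal(as.numeric(table(labTest)), c(1, 1))
  expect_error(makeSplit(tinySegmentSet(nSub = 1, nSeg = 4),
                         "subject_wise"), "at least 2 subjects")
})

test_that("splits are deterministic under the seed", {
  ds <- tinySegmentSet(nSub = 4, nSeg = 5)
  for (mode in c("subject_wise", "per_subject_segments")) {
    p1 <- makeSplit(ds, mode, seed = 42)
    p2 <- makeSplit(ds, mode, seed = 42)
    expect_identical(trainIndices(p1), trainIndices(p2))
    expect_identical(testIndices(p1), testIndices(p2))
    p3 <- makeSplit(ds, mode, seed = 43)
    expect_false(identical(trainIndices(p1), trainIndices(p3)))
  }
})

test_that("metric identities on constructed confusion matrices", {
  ## TP = 3, FP = 1, FN = 2, TN = 4 for the positive class
  y  <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  yh <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  rep <- computeMetrics(y, yh)
  pc <- rep@perClass
  pos <- pc[pc$class == 1L, ]
  expect_equal(pos$tp, 3); expect_equal(pos$fp, 1)
  expect_equal(pos$fn, 2); expect_equal(pos$tn, 4)
  expect_equal(accuracy(rep), 0.7)
  expect_equal(pos$precision, 0.75)
  expect_equal(pos$recall, 0.6)
  expect_equal(pos$f1, 2 * 0.75 * 0.6 / 1.35)
  ## confusion counts always total the number of samples per class view
  expect_true(all(pc$tp + pc$fp + pc$fn + pc$tn == length(y)))
  ## accuracy identity holds exactly
  expect_equal(accuracy(rep), (pos$tp + pos$tn) / length(y))
})

test_that("perfect, anti-perfect and degenerate predictors", {
  y <- c(0, 1, 1, 0, 1)
  perfect <- computeMetrics(y, y)
  expect_equal(accuracy(perfect), 1)
  expect_equal(unname(perfect@weighted), c(1, 1, 1))
  anti <- computeMetrics(y, 1 - y)
  expect_equal(accuracy(anti), 0)
  expect_equal(unname(anti@weighted), c(0, 0, 0))
  ## constant predictor: zero-denominator conventions return 0
  const <- computeMetrics(y, rep(1, 5))
  pc0 <- const@perClass[const@perClass$class == 0L, ]
  expect_equal(pc0$precision, 0)
  expect_equal(pc0$recall, 0)
  expect_equal(pc0$f1, 0)
  expect_error(computeMetrics(c(0, 1), c(0, 1, 1)), "equal length")
  expect_error(computeMetrics(c(0, 2), c(0, 1)), "binary")
})

test_that("weighted aggregates equal accuracy for symmetric confusions", {
  ## equal supports, symmetric confusion matrix
  y  <- c(rep(0, 10), rep(1, 10))
  yh <- c(rep(0, 8), 1, 1, rep(1, 8), 0, 0)
  rep <- computeMetrics(y, yh)
  expect_equal(rep@weighted[["precision"]], accuracy(rep))
  expect_equal(rep@weighted[["recall"]], accuracy(rep))
  expect_equal(rep@weighted[["f1"]], accuracy(rep))
})

test_that("report serialization round-trips the headline numbers", {
  rep <- computeMetrics(c(0, 1, 1, 0), c(0, 1, 0, 0), "toy split", 7L)
  jf <- tempfile(fileext = ".json"); cf <- tempfile(fileext = ".csv")
  writeEvalReport(rep, jf, cf)
  back <- jsonlite::read_json(jf)
  expect_equal(back$accuracy, 0.75)
  expect_equal(back$split, "toy split")
  csv <- utils::read.csv(cf)
  expect_equal(csv$accuracy, 75.00)
  unlink(c(jf, cf))
})
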