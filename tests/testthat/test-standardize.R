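## Per-time-point standardization statistics and their application.

test_that("hand-computed statistics on a single two-channel segment", {
  ## values per time point: t1 -> (1, 3), t2 -> (2, 4)
  seg <- array(0, c(1, 2, 1, 2))
  seg[1, , 1, 1] <- c(1, 3)
  seg[1, , 1, 2] <- c(2, 4)
  x <- segmentSet(seg, 0L, "s1", 128)
  st <- fitStandardization(x)
  expect_equal(st@mu, c(2, 3))
  expect_equal(st@sigma, c(1, 1))    # population cross-channel sd
})

test_that("constant segments hit the epsilon floor and stay finite", {
  seg <- array(5, c(3, 2, 1, 4))
  x <- segmentSet(seg, c(0L, 1L, 0L), c("a", "b", "c"), 128)
  st <- fitStandardization(x)
  expect_equal(st@mu, rep(5, 4))
  expect_equal(st@sigma, rep(1e-8, 4))
  out <- standardize(x, st)
  expect_true(all(is.finite(segments(out))))
  expect_equal(max(abs(segments(out))), 0)
})

test_that("standardization arithmetic and identity statistics", {
  set.seed(2)
  x <- tinySegmentSet(2, 2, 4, 32)
  ident <- new("StandardizationStats", mu = rep(0, 32), sigma = rep(1, 32),
               epsilon = 1e-8)
  expect_equal(segments(standardize(x, ident)), segments(x))
  ## x = 4, mu = 2, sigma = 2 -> 1
  seg <- array(4, c(1, 2, 1, 1))
  st <- new("StandardizationStats", mu = 2, sigma = 2, epsilon = 1e-8)
  expect_equal(as.numeric(segments(standardize(segmentSet(seg, 0L, "s", 1),
                                               st))),
               rep(1, 2))
  expect_error(standardize(x, st), "T = 1")
})

test_that("fitting is deterministic and self-standardization centres data", {
  x <- tinySegmentSet(3, 4, 4, 32, seed = 8)
  s1 <- fitStandardization(x)
  s2 <- fitStandardization(x)
  expect_identical(s1@mu, s2@mu)
  expect_identical(s1@sigma, s2@sigma)
  z <- standardize(x, s1)
  ## refit on the standardized output: mu ~ 0, sigma ~ 1 per time point
  s3 <- fitStandardization(z)
  expect_lt(max(abs(s3@mu)), 1e-6)
  expect_lt(max(abs(s3@sigma - 1)), 1e-3)
})

test_that("global dialect pools channels and segments", {
  x <- tinySegmentSet(2, 3, 4, 32, seed = 4)
  st <- fitStandardization(x, dialect = "global")
  seg <- segments(x)
  t1 <- as.numeric(seg[, , 1, 1])
  expect_equal(st@mu[1], mean(t1))
  expect_equal(st@sigma[1], sqrt(mean(t1^2) - mean(t1)^2))
})

test_that("empty input is rejected", {
  empty <- segmentSet(array(0, c(0, 2, 1, 4)), integer(0), character(0), 128)
  expect_error(fitStandardization(empty), "empty")
})
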