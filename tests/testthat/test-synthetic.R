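test_that("dataset bookkeeping: counts, balance, subject consistency", {
  ds <- generateDataset(syntheticSpec(
    nSubjectsPerClass = 2, segmentsPerSubject = 3, nChannels = 4,
    samplingRate = 128, segmentLength = 256, seed = 11))
  expect_equal(nSegments(ds), 12L)
  expect_equal(dim(segments(ds)), c(12L, 4L, 1L, 256L))
  expect_equal(length(unique(subjectIds(ds))), 4L)
  expect_equal(sum(labels(ds) == 0L), 6L)
  expect_equal(sum(labels(ds) == 1L), 6L)
  ## no subject carries two labels
  expect_true(all(vapply(split(labels(ds), subjectIds(ds)),
                         function(l) length(unique(l)) == 1L, logical(1))))
})

test_that("identical (spec, seed) pairs give bit-identical data", {
  spec <- syntheticSpec(nSubjectsPerClass = 2, segmentsPerSubject = 2,
                        nChannels = 3, segmentLength = 64, seed = 99)
  expect_identical(segments(generateDataset(spec)),
                   segments(generateDataset(spec)))
  expect_identical(signalData(generateRawRecording(spec)),
                   signalData(generateRawRecording(spec)))
})

test_that("generator RNG is scoped and does not disturb the caller stream", {
  set.seed(123)
  a <- rnorm(3)
  set.seed(123)
  invisible(generateDataset(syntheticSpec(nSubjectsPerClass = 1,
                                          segmentsPerSubject = 1,
                                          nChannels = 2,
                                          segmentLength = 32)))
  expect_identical(a, rnorm(3))
})

test_that("measured band-power contrast tracks the powerRatio knob", {
  ## >= 100 segments; periodogram oracle measures the 8-12 Hz class ratio
  ds2 <- generateDataset(syntheticSpec(
    nSubjectsPerClass = 10, segmentsPerSubject = 6, nChannels = 4,
    powerRatio = 2, seed = 5))
  r2 <- bandPowerRatio(ds2, c(8, 12))$ratio
  expect_gt(r2, 1.6)
  expect_lt(r2, 2.4)
  ## powerRatio = 1: no separable signal
  ds1 <- generateDataset(syntheticSpec(
    nSubjectsPerClass = 10, segmentsPerSubject = 6, nChannels = 4,
    powerRatio = 1, seed = 5))
  r1 <- bandPowerRatio(ds1, c(8, 12))$ratio
  expect_gt(r1, 0.8)
  expect_lt(r1, 1.25)
})

test_that("oscillation power is concentrated in the target band", {
  ds <- generateDataset(syntheticSpec(
    nSubjectsPerClass = 10, segmentsPerSubject = 5, nChannels = 4,
    powerRatio = 2, seed = 3))
  inBand <- bandPowerRatio(ds, c(8, 12))
  outBand <- bandPowerRatio(ds, c(30, 50))
  ## the class contrast exists only inside the target band
  expect_gt(inBand$ratio, 1.5)
  expect_lt(abs(outBand$ratio - 1), 0.3)
  ## in-band power dominates an equally wide out-of-band stretch
  expect_gt(inBand$class0 / outBand$class0, 3)
})

test_that("raw recordings expose line noise and drift to the FFT", {
  base <- syntheticSpec(nSubjectsPerClass = 1, segmentsPerSubject = 4,
                        nChannels = 2, samplingRate = 1000,
                        segmentLength = 1000, targetBand = c(8, 12),
                        seed = 21)
  peakFreq <- function(rec) {
    x <- signalData(rec)[1, ]
    n <- length(x)
    f <- seq(0, samplingRate(rec), length.out = n + 1)[seq_len(n)]
    keep <- f > 1 & f < samplingRate(rec) / 2
    sp <- Mod(fft(x))^2
    f[keep][which.max(sp[keep])]
  }
  ## clean recording: no 50 Hz peak above the noise floor
  clean <- generateRawRecording(base)
  x <- signalData(clean)[1, ]
  n <- length(x)
  f <- seq(0, 1000, length.out = n + 1)[seq_len(n)]
  sp <- Mod(fft(x))^2
  at50 <- max(sp[abs(f - 50) < 0.5])
  nearby <- stats::median(sp[f > 40 & f < 60])
  expect_lt(at50, 20 * nearby)
  ## strong mains component dominates the spectrum
  noisy <- generateRawRecording(
    syntheticSpec(nSubjectsPerClass = 1, segmentsPerSubject = 4,
                  nChannels = 2, samplingRate = 1000, segmentLength = 1000,
                  targetBand = c(8, 12), lineNoiseAmplitude = 10, seed = 21))
  expect_lt(abs(peakFreq(noisy) - 50), 1.1)
})

test_that("invalid specs are rejected", {
  expect_error(syntheticSpec(nSubjectsPerClass = 0), "nSubjectsPerClass")
  expect_error(syntheticSpec(targetBand = c(8, 70), samplingRate = 128),
               "targetBand")
  expect_error(syntheticSpec(powerRatio = 0.5), "powerRatio")
  expect_error(syntheticSpec(segmentLength = 16, targetBand = c(8, 12),
                             samplingRate = 128), "two cycles")
})
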