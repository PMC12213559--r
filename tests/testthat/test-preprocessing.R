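## Spectral and arithmetic contracts of the conditioning chain.

toneRecord <- function(freq, fs = 1000, secs = 4, channels = 2,
                       amplitude = 1) {
  tt <- (seq_len(fs * secs) - 1) / fs
  dat <- matrix(rep(amplitude * sin(2 * pi * freq * tt), channels),
                nrow = channels, byrow = TRUE)
  eegRecord(dat, fs)
}

## RMS over the middle 60% to avoid filter edge transients
midRms <- function(rec) {
  x <- signalData(rec)[1, ]
  n <- length(x)
  sqrt(mean(x[floor(0.2 * n):ceiling(0.8 * n)]^2))
}

test_that("notch filter kills the mains tone and spares the passband", {
  tone50 <- toneRecord(50)
  expect_lt(midRms(notchFilter(tone50, 50)), 0.1 * midRms(tone50))
  tone10 <- toneRecord(10)
  expect_lt(abs(midRms(notchFilter(tone10, 50)) / midRms(tone10) - 1), 0.1)
  ## 5 Hz away from the notch: attenuation < 1 dB
  tone45 <- toneRecord(45)
  ratio <- midRms(notchFilter(tone45, 50)) / midRms(tone45)
  expect_gt(20 * log10(ratio), -1)
  zero <- eegRecord(matrix(0, 2, 2000), 1000)
  expect_equal(max(abs(signalData(notchFilter(zero, 50)))), 0)
  expect_error(notchFilter(tone50, 600), "Nyquist|samplingRate")
})

test_that("bandpass filter removes DC/drift and preserves mid-band", {
  ## long record: the 0.5 Hz high-pass transient decays over seconds
  dc <- eegRecord(matrix(1, 2, 30000), 1000)
  out <- bandpassFilter(dc, 0.5, 64)
  expect_lt(midRms(out), 0.01)
  tone10 <- toneRecord(10)
  expect_lt(abs(midRms(bandpassFilter(tone10, 0.5, 64)) / midRms(tone10) - 1),
            0.1)
  ## sub-low drift attenuated >= 20 dB
  drift <- toneRecord(0.1, secs = 30)
  ratio <- midRms(bandpassFilter(drift, 0.5, 64)) / midRms(drift)
  expect_lt(20 * log10(ratio), -20)
  expect_error(bandpassFilter(tone10, 0.5, 500), "band edges")
  expect_error(bandpassFilter(tone10, 0, 64), "band edges")
})

test_that("filters are linear operators", {
  set.seed(7)
  n <- 2000
  x <- matrix(rnorm(2 * n), 2)
  y <- matrix(rnorm(2 * n), 2)
  a <- 1.7; b <- -0.6
  for (f in list(function(r) notchFilter(r, 50),
                 function(r) bandpassFilter(r, 0.5, 64))) {
    fx <- signalData(f(eegRecord(x, 1000)))
    fy <- signalData(f(eegRecord(y, 1000)))
    fxy <- signalData(f(eegRecord(a * x + b * y, 1000)))
    ## relative to the output scale (narrow IIR poles amplify roundoff)
    expect_lt(max(abs(fxy - (a * fx + b * fy))) / max(abs(fxy)), 1e-6)
  }
})

test_that("resampling has exact output length and preserves tones", {
  rec <- eegRecord(matrix(rnorm(2 * 10000), 2), 1000)
  out <- resampleRecord(rec, 128)
  expect_equal(ncol(signalData(out)), 1280L)   # round(10000 * 128/1000)
  expect_equal(samplingRate(out), 128)
  ## 10 Hz tone survives the rate change within 10% RMS
  tone <- toneRecord(10, secs = 10)
  down <- resampleRecord(tone, 128)
  expect_lt(abs(midRms(down) / midRms(tone) - 1), 0.1)
  ## identity when the rate is unchanged
  expect_identical(signalData(resampleRecord(rec, 1000)), signalData(rec))
  ## odd ratio still rounds
  expect_equal(ncol(signalData(resampleRecord(rec, 333))), 3330L)
  expect_error(resampleRecord(rec, -1), "positive")
})

test_that("resampling suppresses content above the target Nyquist", {
  ## 100 Hz tone cannot survive resampling to 128 Hz (Nyquist 64)
  tone <- toneRecord(100, secs = 5)
  down <- resampleRecord(tone, 128)
  expect_lt(midRms(down), 0.1 * midRms(tone))
})

test_that("re-referencing subtracts the reference mean", {
  dat <- matrix(c(1, 3, 5), 3, 10)
  rec <- eegRecord(dat, 100, channelNames = c("A", "B", "C"))
  ## hand arithmetic: mean of refs {A, B} is 2 -> channels (-1, 1, 3)
  out <- rereference(rec, c("A", "B"), dropRefs = FALSE)
  expect_equal(signalData(out)[, 1], c(-1, 1, 3))
  ## zero reference leaves the data unchanged
  z <- eegRecord(rbind(0, dat), 100, channelNames = c("Z", "A", "B", "C"))
  expect_equal(signalData(rereference(z, "Z", dropRefs = FALSE)),
               signalData(z))
  ## reference channels dropped by default
  dropped <- rereference(rec, c("A", "B"))
  expect_equal(channelNames(dropped), "C")
  expect_equal(nrow(signalData(dropped)), 1L)
  expect_error(rereference(rec, "ZZ"), "unknown reference")
})

test_that("segmentation window arithmetic", {
  rec <- eegRecord(matrix(rnorm(2000), 2), 100)
  expect_equal(nSegments(segmentRecord(rec, 256, 256)), 3L)
  expect_equal(nSegments(segmentRecord(rec, 256, 128)), 6L)
  one <- segmentRecord(rec, 1000, 1000)
  expect_equal(nSegments(one), 1L)
  expect_equal(matrix(segments(one)[1, , 1, ], 2), signalData(rec))
  ## overlapping windows share the expected samples
  ov <- segments(segmentRecord(rec, 256, 128))
  expect_equal(ov[1, , 1, 129:256], ov[2, , 1, 1:128])
  ## labels and subject ids inherited
  expect_equal(labels(segmentRecord(rec, 500, 500)), c(0L, 0L))
  expect_error(segmentRecord(rec, 5000), "length")
})

test_that("full chain preserves channel count, finiteness and a 10 Hz tone", {
  spec <- syntheticSpec(nSubjectsPerClass = 1, segmentsPerSubject = 2,
                        nChannels = 4, samplingRate = 1000,
                        segmentLength = 2000, targetBand = c(8, 12),
                        lineNoiseAmplitude = 2, driftAmplitude = 3,
                        seed = 31)
  rec <- generateRawRecording(spec)
  seg <- preprocessChain(rec, notch = 50, band = c(0.5, 64),
                         resampleTo = 128, segmentLength = 128L)
  expect_equal(dim(segments(seg))[2], 4L)
  expect_true(all(is.finite(segments(seg))))
  expect_equal(samplingRate(seg), 128)
  ## a pure 10 Hz tone passes the whole chain within 1 dB
  tone <- toneRecord(10, secs = 8)
  out <- resampleRecord(bandpassFilter(notchFilter(tone, 50), 0.5, 64), 128)
  expect_gt(20 * log10(midRms(out) / midRms(tone)), -1)
})
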