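## Synthetic two-class EEG.
##
## Signal model per channel: a 1/f-shaped Gaussian background plus a shared
## band-limited oscillation source mixed into all channels with fixed
## per-subject weights.  The class difference is purely multiplicative on
## the oscillation amplitude (class 1 amplitude = class 0 amplitude *
## sqrt(powerRatio)), giving a single separability knob measured in band
## power.  Subjects differ through a log-normal amplitude jitter and
## through their mixing weights, which makes subject-wise splits genuinely
## harder than segment-wise ones.

#' Describe a synthetic two-class EEG dataset
#'
#' The defaults encode the reference study conditions used throughout the
#' package's evaluation: 20 subjects per class, 50 eyes-closed-style
#' segments each, 8 channels at 128 Hz, 256-sample segments, an 8-12 Hz
#' alpha-band oscillation whose power is doubled in class 1.
#'
#' @param nSubjectsPerClass subjects per class.
#' @param segmentsPerSubject segments per subject.
#' @param nChannels channel count (32 and 61 mirror the two real montages;
#'   the default 8 keeps simulated experiments light).
#' @param samplingRate sampling rate in Hz (128 for preprocessed-style data,
#'   1000 for raw-style recordings).
#' @param segmentLength segment length in samples; must fit at least two
#'   cycles of the slowest target-band component.
#' @param targetBand oscillation band (low, high) in Hz.
#' @param powerRatio class-1 / class-0 oscillatory band-power ratio (>= 1;
#'   1 means no separable signal).
#' @param noiseFloor RMS amplitude of the background; the class-0
#'   oscillation source uses the same RMS, so in-band power is dominated by
#'   the oscillation.
#' @param lineNoiseAmplitude amplitude of an optional 50 Hz mains sinusoid
#'   (raw recordings).
#' @param driftAmplitude amplitude of an optional sub-0.5 Hz drift
#'   component (raw recordings).
#' @param seed integer RNG seed; identical (spec, seed) pairs give
#'   bit-identical data.
#' @return a [SyntheticSpec-class].
#' @examples
#' spec <- syntheticSpec(nSubjectsPerClass = 2, segmentsPerSubject = 3,
#'                       nChannels = 4)
#' ds <- generateDataset(spec)
#' ds
#' @export
syntheticSpec <- function(nSubjectsPerClass = 20L, segmentsPerSubject = 50L,
                          nChannels = 8L, samplingRate = 128,
                          segmentLength = 256L, targetBand = c(8, 12),
                          powerRatio = 2, noiseFloor = 1,
                          lineNoiseAmplitude = 0, driftAmplitude = 0,
                          seed = 1L) {
  new("SyntheticSpec",
      nSubjectsPerClass = as.integer(nSubjectsPerClass),
      segmentsPerSubject = as.integer(segmentsPerSubject),
      nChannels = as.integer(nChannels),
      samplingRate = as.numeric(samplingRate),
      segmentLength = as.integer(segmentLength),
      targetBand = as.numeric(targetBand),
      powerRatio = as.numeric(powerRatio),
      noiseFloor = as.numeric(noiseFloor),
      lineNoiseAmplitude = as.numeric(lineNoiseAmplitude),
      driftAmplitude = as.numeric(driftAmplitude),
      seed = as.integer(seed))
}

## 1/f-shaped Gaussian noise of length n, unit RMS, via spectral shaping.
pinkNoise <- function(n, samplingRate) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- seq(0, samplingRate, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, samplingRate - f)           # two-sided frequency magnitude
  shape <- 1 / sqrt(pmax(f, 1))            # flat below 1 Hz, 1/f above
  x <- Re(stats::fft(sp * shape, inverse = TRUE)) / n
  x / max(stats::sd(x), .Machine$double.eps)
}

## band-limited Gaussian oscillation of length n, unit RMS
bandNoise <- function(n, samplingRate, band) {
  pad <- max(64L, ceiling(2 * samplingRate / band[1]))
  w <- stats::rnorm(n + 2L * pad)
  bf <- signal::butter(4, band / (samplingRate / 2), type = "pass")
  x <- signal::filtfilt(bf, w)[pad + seq_len(n)]
  x / max(stats::sd(x), .Machine$double.eps)
}

## Per-subject fixed properties drawn from the active RNG stream.  The
## mixing vector is normalized to unit mean square so it shapes the
## cross-channel profile without adding subject-level gain: the log-normal
## amplitude jitter is the only subject-level amplitude factor.
drawSubject <- function(spec) {
  mix <- stats::runif(spec@nChannels, 0.5, 1.5)
  mix <- mix * sqrt(spec@nChannels / sum(mix^2))
  list(mix = mix, amp = exp(stats::rnorm(1, 0, 0.1)))
}

## one (C x T) segment for a subject of class `label`
drawSegmentMatrix <- function(spec, subject, label) {
  C <- spec@nChannels
  T <- spec@segmentLength
  oscAmp <- spec@noiseFloor * subject$amp *
    if (label == 1L) sqrt(spec@powerRatio) else 1
  src <- bandNoise(T, spec@samplingRate, spec@targetBand)
  seg <- matrix(0, C, T)
  for (c in seq_len(C)) {
    seg[c, ] <- spec@noiseFloor * pinkNoise(T, spec@samplingRate) +
      oscAmp * subject$mix[c] * src
  }
  seg
}

#' Generate a labeled synthetic SegmentSet
#'
#' Draws `2 * nSubjectsPerClass` subjects (class-balanced, unique and
#' class-consistent subject identifiers) with `segmentsPerSubject` segments
#' each.  Class-1 subjects carry target-band oscillatory power elevated by
#' `powerRatio`; a log-normal per-subject amplitude jitter (sd 0.1 on the
#' log scale) keeps subjects non-identical.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a [SegmentSet-class] with
#'   `2 * nSubjectsPerClass * segmentsPerSubject` segments.
#' @seealso [generateRawRecording()] for continuous raw-style recordings.
#' @export
generateDataset <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  nSub <- spec@nSubjectsPerClass
  nSeg <- spec@segmentsPerSubject
  C <- spec@nChannels
  T <- spec@segmentLength
  N <- 2L * nSub * nSeg
  withSeed(spec@seed, {
    seg <- array(0, dim = c(N, C, 1L, T))
    labs <- integer(N)
    subj <- character(N)
    i <- 0L
    for (label in c(0L, 1L)) {
      for (s in seq_len(nSub)) {
        sid <- sprintf("sub%03d_c%d", s + label * nSub, label)
        sub <- drawSubject(spec)
        for (k in seq_len(nSeg)) {
          i <- i + 1L
          seg[i, , 1L, ] <- drawSegmentMatrix(spec, sub, label)
          labs[i] <- label
          subj[i] <- sid
        }
      }
    }
    segmentSet(seg, labs, subj, spec@samplingRate)
  })
}

#' Generate one continuous raw-style recording
#'
#' Produces a single unsegmented [EEGRecord-class] of
#' `segmentsPerSubject * segmentLength` samples with the same signal model
#' as [generateDataset()], plus optional 50 Hz line noise and sub-0.5 Hz
#' drift so that the full preprocessing chain can be exercised end to end.
#' Intended for raw-style sampling rates (e.g. 1000 Hz).
#'
#' @param spec a [SyntheticSpec-class]; `lineNoiseAmplitude` and
#'   `driftAmplitude` control the artifact components.
#' @param label class label of the simulated subject.
#' @param subjectId subject identifier.
#' @return an [EEGRecord-class].
#' @export
generateRawRecording <- function(spec, label = 0L, subjectId = "raw01") {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  C <- spec@nChannels
  n <- spec@segmentsPerSubject * spec@segmentLength
  fs <- spec@samplingRate
  withSeed(spec@seed, {
    sub <- drawSubject(spec)
    oscAmp <- spec@noiseFloor * sub$amp *
      if (label == 1L) sqrt(spec@powerRatio) else 1
    src <- bandNoise(n, fs, spec@targetBand)
    tt <- (seq_len(n) - 1L) / fs
    dat <- matrix(0, C, n)
    for (c in seq_len(C)) {
      x <- spec@noiseFloor * pinkNoise(n, fs) + oscAmp * sub$mix[c] * src
      if (spec@lineNoiseAmplitude > 0) {
        x <- x + spec@lineNoiseAmplitude *
          sin(2 * pi * 50 * tt + stats::runif(1, 0, 2 * pi))
      }
      if (spec@driftAmplitude > 0) {
        x <- x + spec@driftAmplitude *
          (sin(2 * pi * 0.1 * tt + stats::runif(1, 0, 2 * pi)) +
             0.5 * sin(2 * pi * 0.3 * tt + stats::runif(1, 0, 2 * pi)))
      }
      dat[c, ] <- x
    }
    eegRecord(dat, fs, subjectId = subjectId, label = label)
  })
}

#' Mean band power of a SegmentSet by class
#'
#' Periodogram-based mean power inside a frequency band, averaged over
#' segments and channels, reported per class together with their ratio.
#' Useful for checking the separability knob of the generator.
#'
#' @param x a [SegmentSet-class].
#' @param band numeric length-2 band (low, high) in Hz.
#' @return named list with `class0`, `class1` mean band power and `ratio`
#'   (`class1 / class0`; NA when a class is absent).
#' @export
bandPowerRatio <- function(x, band = c(8, 12)) {
  stopifnot(is(x, "SegmentSet"))
  seg <- x@segments
  d <- dim(seg)
  T <- d[4]
  f <- seq(0, x@samplingRate, length.out = T + 1)[seq_len(T)]
  sel <- which(f >= band[1] & f <= band[2])
  pow <- numeric(d[1])
  for (i in seq_len(d[1])) {
    m <- matrix(seg[i, , 1L, ], nrow = d[2])
    sp <- Mod(stats::mvfft(t(m)))^2 / T     # per-channel periodogram
    pow[i] <- mean(sp[sel, ])
  }
  p0 <- mean(pow[x@labels == 0L])
  p1 <- mean(pow[x@labels == 1L])
  list(class0 = p0, class1 = p1, ratio = p1 / p0)
}
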