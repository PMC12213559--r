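## Internal helpers: scoped RNG, array layout conversions, activation.

## Run code under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## SegmentSet (N x C x 1 x T) -> compute layout (C x T x N)
segmentsToCube <- function(seg) {
  d <- dim(seg)
  aperm(array(seg, dim = d[c(1, 2, 4)]), c(2, 3, 1))
}

## compute layout (C x T x N) -> SegmentSet layout (N x C x 1 x T)
cubeToSegments <- function(x) {
  d <- dim(x)
  array(aperm(x, c(3, 1, 2)), dim = c(d[3], d[1], 1L, d[2]))
}

## exact GELU on plain matrices/vectors (small classifier tensors)
geluMat <- function(x) x * stats::pnorm(x)
geluGradMat <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

## concatenate two (C x T x N) cubes along the channel axis
catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

## tiny FNV-1a hash of a character scalar, for stamping configs into logs
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    ## xor the low byte only (b < 256); h itself may exceed integer range
    lowByte <- h %% 256
    h <- h - lowByte + bitwXor(as.integer(lowByte), as.integer(b))
    ## h * 16777619 mod 2^32 without exceeding double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

dscnetLog <- function(level, ..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf("[dscnet %s] %s", level, sprintf(...)))
}
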