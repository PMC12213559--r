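# Explicit-loop reference implementations of every network operation.
# These are deliberately written as naive nested loops over the stated
# contracts (zero-padded same convolution, grouped channel ranges, softmax
# over the k-neighbourhood, ...) and share no code with the package's
# compute path.

oracleConv1d <- function(x, w, b, groups = 1L) {
  Cin <- dim(x)[1]; Tn <- dim(x)[2]; N <- dim(x)[3]
  Cout <- dim(w)[1]; Cing <- dim(w)[2]; k <- dim(w)[3]
  off <- k %/% 2
  Coutg <- Cout / groups
  y <- array(0, c(Cout, Tn, N))
  for (n in seq_len(N)) {
    for (g in seq_len(groups)) {
      for (oc in seq_len(Coutg)) {
        o <- (g - 1L) * Coutg + oc
        for (t in seq_len(Tn)) {
          acc <- b[o]
          for (ic in seq_len(Cing)) {
            for (j in seq_len(k)) {
              u <- t + (j - 1L - off)
              if (u >= 1L && u <= Tn) {
                acc <- acc + w[o, ic, j] * x[(g - 1L) * Cing + ic, u, n]
              }
            }
          }
          y[o, t, n] <- acc
        }
      }
    }
  }
  y
}

oracleMaxpool <- function(x, p) {
  To <- dim(x)[2] %/% p
  y <- array(0, c(dim(x)[1], To, dim(x)[3]))
  for (n in seq_len(dim(x)[3])) {
    for (t in seq_len(To)) {
      for (c in seq_len(dim(x)[1])) {
        y[c, t, n] <- max(x[c, (t - 1L) * p + seq_len(p), n])
      }
    }
  }
  y
}

oracleUpsampleNN <- function(x, p, tOut) {
  Tin <- dim(x)[2]
  y <- array(0, c(dim(x)[1], tOut, dim(x)[3]))
  for (t in seq_len(tOut)) {
    src <- min((t - 1L) %/% p + 1L, Tin)
    y[, t, ] <- x[, src, , drop = FALSE]
  }
  y
}

oracleGelu <- function(z) z * pnorm(z)

oracleDsc <- function(x, rw) {
  h <- oracleConv1d(x, rw$dw$w, rw$dw$b, groups = dim(x)[1])
  oracleConv1d(h, rw$pw$w, rw$pw$b, groups = 1L)
}

oracleSc <- function(x, rw) oracleConv1d(x, rw$sc$w, rw$sc$b, 1L)

# DAFM: channel split, per-level depthwise conv with temporal max-pool /
# nearest-neighbour upsampling, 1x1 fusion, GELU-gated modulation.
oracleDafm <- function(x, w, cfg) {
  C <- dim(x)[1]; Tn <- dim(x)[2]
  L <- cfg@nLevels
  cw <- C %/% L
  xc <- array(0, dim(x))
  for (j in seq_len(L)) {
    rng <- (j - 1L) * cw + seq_len(cw)
    fj <- min(cfg@dafmPool^(j - 1L), Tn)
    xj <- x[rng, , , drop = FALSE]
    if (fj > 1L) {
      pooled <- oracleMaxpool(xj, fj)
      conv <- oracleConv1d(pooled, w$dw[[j]]$w, w$dw[[j]]$b, groups = cw)
      xc[rng, , ] <- oracleUpsampleNN(conv, fj, Tn)
    } else {
      xc[rng, , ] <- oracleConv1d(xj, w$dw[[j]]$w, w$dw[[j]]$b, groups = cw)
    }
  }
  xhat <- oracleConv1d(xc, w$fuse$w, w$fuse$b, 1L)
  oracleGelu(xhat) * x
}

# CoT: grouped 1xk static context K1; attention logits from two stacked
# 1x1 convolutions on [K1, Q = x]; softmax over the k taps; K2 aggregates
# V over each position's neighbourhood; Y = K1 + K2.
oracleCot <- function(x, w, cfg) {
  C <- dim(x)[1]; Tn <- dim(x)[2]; N <- dim(x)[3]
  k <- cfg@cotKernel
  off <- k %/% 2
  k1 <- oracleConv1d(x, w$k1$w, w$k1$b, groups = cfg@cotGroups)
  qk <- array(0, c(2L * C, Tn, N))
  qk[seq_len(C), , ] <- k1
  qk[C + seq_len(C), , ] <- x
  a1 <- oracleGelu(oracleConv1d(qk, w$attn1$w, w$attn1$b, 1L))
  logits <- oracleConv1d(a1, w$attn2$w, w$attn2$b, 1L)
  v <- oracleConv1d(x, w$v$w, w$v$b, 1L)
  y <- k1
  for (n in seq_len(N)) {
    for (t in seq_len(Tn)) {
      for (c in seq_len(C)) {
        lg <- logits[(c - 1L) * k + seq_len(k), t, n]
        p <- exp(lg - max(lg)); p <- p / sum(p)
        acc <- 0
        for (j in seq_len(k)) {
          u <- t + (j - 1L - off)
          if (u >= 1L && u <= Tn) acc <- acc + p[j] * v[c, u, n]
        }
        y[c, t, n] <- y[c, t, n] + acc
      }
    }
  }
  y
}

oracleClassify <- function(x, w) {
  C <- dim(x)[1]; N <- dim(x)[3]
  gap <- matrix(0, C, N)
  for (n in seq_len(N)) for (c in seq_len(C)) gap[c, n] <- mean(x[c, , n])
  z1 <- w$fc1$w %*% gap + matrix(w$fc1$b, nrow(w$fc1$w), N)
  a1 <- oracleGelu(z1)
  w$fc2$w %*% a1 + matrix(w$fc2$b, nrow(w$fc2$w), N)
}

oracleRound <- function(x, rw, cfg) {
  h <- if (cfg@convType == "dsc") oracleDsc(x, rw) else oracleSc(x, rw)
  br <- NULL
  if (cfg@useDafm) br <- oracleDafm(h, rw$dafm, cfg)
  if (cfg@useCot) {
    cy <- oracleCot(h, rw$cot, cfg)
    br <- if (is.null(br)) cy else br + cy
  }
  if (is.null(br)) br <- h
  oracleMaxpool(br, cfg@maxpoolSize)
}

# replace every weight/bias leaf with fresh N(0, 0.4) draws so biases are
# exercised too
randomizeWeights <- function(store, seed) {
  store@weights <- dscnet:::mapLeaves(function(a) {
    out <- rnorm(length(a), 0, 0.4)
    if (!is.null(dim(a))) dim(out) <- dim(a)
    out
  }, store@weights)
  store
}

randomCube <- function(C, Tn, N, sd = 1) array(rnorm(C * Tn * N, 0, sd),
                                               c(C, Tn, N))

smallConfig <- function(...) {
  dscnetConfig(inChannels = 4L, embedWidth = 4L, stage2Width = 8L,
               cotGroups = 2L, classifierHidden = 8L, ...)
}

tinySegmentSet <- function(nSub = 2L, nSeg = 3L, C = 4L, Tn = 32L,
                           seed = 1L) {
  generateDataset(syntheticSpec(
    nSubjectsPerClass = nSub, segmentsPerSubject = nSeg, nChannels = C,
    samplingRate = 128, segmentLength = Tn, seed = seed))
}
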