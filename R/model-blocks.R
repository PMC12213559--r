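## Network blocks: forward passes with caches and the matching analytic
## backward passes.  Feature maps are (C x T x N) arrays (the singleton
## height axis of the (C x 1 x T) layout is implicit); every gradient
## structure mirrors the weight structure by name.

bnEps <- 1e-5

convF <- function(x, p, groups = 1L) {
  conv1dForwardCpp(x, p$w, p$b, as.integer(groups))
}

convB <- function(x, p, dy, groups = 1L) {
  r <- conv1dBackwardCpp(x, p$w, dy, as.integer(groups))
  list(dx = r$dx, g = list(w = r$dw, b = as.numeric(r$db)))
}

## ---------------------------------------------------------------- stage 1

embedF <- function(x, w, st, training) {
  c1 <- convF(x, w$conv1)
  b1 <- bnForwardCpp(c1, w$bn1$gamma, w$bn1$beta, st$bn1$mean, st$bn1$var,
                     training, bnEps)
  a1 <- geluCpp(b1$y)
  c2 <- convF(a1, w$conv2)
  b2 <- bnForwardCpp(c2, w$bn2$gamma, w$bn2$beta, st$bn2$mean, st$bn2$var,
                     training, bnEps)
  a2 <- geluCpp(b2$y)
  c3 <- convF(a2, w$conv3)
  b3 <- bnForwardCpp(c3, w$bn3$gamma, w$bn3$beta, st$bn3$mean, st$bn3$var,
                     training, bnEps)
  a3 <- geluCpp(b3$y)
  res <- a3 + convF(x, w$skip)
  proj <- convF(x, w$proj)
  list(y = catChannels(res, proj),
       cache = list(x = x, a1 = a1, a2 = a2, b1 = b1, b2 = b2, b3 = b3))
}

embedB <- function(cache, w, dy) {
  E <- dim(w$conv1$w)[1]
  dres <- dy[seq_len(E), , , drop = FALSE]
  dproj <- dy[E + seq_len(E), , , drop = FALSE]
  pb <- convB(cache$x, w$proj, dproj)
  sb <- convB(cache$x, w$skip, dres)
  dx <- pb$dx + sb$dx
  dz3 <- dres * geluGradCpp(cache$b3$y)
  n3 <- bnBackwardCpp(dz3, cache$b3$xhat, cache$b3$invstd, w$bn3$gamma)
  c3b <- convB(cache$a2, w$conv3, n3$dx)
  dz2 <- c3b$dx * geluGradCpp(cache$b2$y)
  n2 <- bnBackwardCpp(dz2, cache$b2$xhat, cache$b2$invstd, w$bn2$gamma)
  c2b <- convB(cache$a1, w$conv2, n2$dx)
  dz1 <- c2b$dx * geluGradCpp(cache$b1$y)
  n1 <- bnBackwardCpp(dz1, cache$b1$xhat, cache$b1$invstd, w$bn1$gamma)
  c1b <- convB(cache$x, w$conv1, n1$dx)
  dx <- dx + c1b$dx
  list(dx = dx,
       g = list(conv1 = c1b$g,
                bn1 = list(gamma = as.numeric(n1$dgamma),
                           beta = as.numeric(n1$dbeta)),
                conv2 = c2b$g,
                bn2 = list(gamma = as.numeric(n2$dgamma),
                           beta = as.numeric(n2$dbeta)),
                conv3 = c3b$g,
                bn3 = list(gamma = as.numeric(n3$dgamma),
                           beta = as.numeric(n3$dbeta)),
                skip = sb$g, proj = pb$g))
}

## gelu is applied to the bn OUTPUT, so the gelu gradient needs b*$y, not
## the conv output; embedB above therefore uses cache$b*$y.

## ------------------------------------------- stage 2: convolutional front

convStepF <- function(x, rw, cfg) {
  if (cfg@convType == "dsc") {
    h <- convF(x, rw$dw, groups = dim(x)[1])
    list(y = convF(h, rw$pw), cache = list(x = x, h = h))
  } else {
    list(y = convF(x, rw$sc), cache = list(x = x))
  }
}

convStepB <- function(cache, rw, cfg, dy) {
  if (cfg@convType == "dsc") {
    pb <- convB(cache$h, rw$pw, dy)
    db <- convB(cache$x, rw$dw, pb$dx, groups = dim(cache$x)[1])
    list(dx = db$dx, g = list(dw = db$g, pw = pb$g))
  } else {
    sb <- convB(cache$x, rw$sc, dy)
    list(dx = sb$dx, g = list(sc = sb$g))
  }
}

## --------------------------------------------------- stage 2: DAFM branch

dafmLevelFactors <- function(cfg, T) {
  pmin(cfg@dafmPool^(seq_len(cfg@nLevels) - 1L), T)
}

dafmF <- function(h, w, cfg) {
  d <- dim(h)
  C <- d[1]; T <- d[2]
  L <- cfg@nLevels
  cw <- C %/% L
  fac <- dafmLevelFactors(cfg, T)
  xc <- array(0, dim = d)
  branches <- vector("list", L)
  for (j in seq_len(L)) {
    rng <- (j - 1L) * cw + seq_len(cw)
    xj <- h[rng, , , drop = FALSE]
    if (fac[j] > 1L) {
      mp <- maxpoolForwardCpp(xj, fac[j])
      dj <- convF(mp$y, w$dw[[j]], groups = cw)
      xc[rng, , ] <- upsampleForwardCpp(dj, fac[j], T)
      branches[[j]] <- list(input = mp$y, idx = mp$idx)
    } else {
      xc[rng, , ] <- convF(xj, w$dw[[j]], groups = cw)
      branches[[j]] <- list(input = xj)
    }
  }
  xhat <- convF(xc, w$fuse)
  gmap <- geluCpp(xhat)
  list(y = gmap * h,
       cache = list(h = h, branches = branches, xc = xc, xhat = xhat,
                    gmap = gmap, fac = fac, cw = cw))
}

dafmB <- function(cache, w, cfg, dy) {
  h <- cache$h
  T <- dim(h)[2]
  dgmap <- dy * h
  dh <- dy * cache$gmap
  dxhat <- dgmap * geluGradCpp(cache$xhat)
  fb <- convB(cache$xc, w$fuse, dxhat)
  gdw <- vector("list", cfg@nLevels)
  for (j in seq_len(cfg@nLevels)) {
    rng <- (j - 1L) * cache$cw + seq_len(cache$cw)
    duj <- fb$dx[rng, , , drop = FALSE]
    br <- cache$branches[[j]]
    if (cache$fac[j] > 1L) {
      dd <- upsampleBackwardCpp(duj, cache$fac[j], dim(br$input)[2])
      cb <- convB(br$input, w$dw[[j]], dd, groups = cache$cw)
      dxj <- maxpoolBackwardCpp(cb$dx, br$idx, T)
    } else {
      cb <- convB(br$input, w$dw[[j]], duj, groups = cache$cw)
      dxj <- cb$dx
    }
    gdw[[j]] <- cb$g
    dh[rng, , ] <- dh[rng, , , drop = FALSE] + dxj
  }
  names(gdw) <- names(w$dw)
  list(dx = dh, g = list(dw = gdw, fuse = fb$g))
}

## ---------------------------------------------------- stage 2: CoT branch

cotF <- function(h, w, cfg) {
  k <- cfg@cotKernel
  k1 <- convF(h, w$k1, groups = cfg@cotGroups)
  qk <- catChannels(k1, h)
  a1p <- convF(qk, w$attn1)
  a1 <- geluCpp(a1p)
  logits <- convF(a1, w$attn2)
  v <- convF(h, w$v)
  agg <- cotAggForwardCpp(logits, v, k)
  list(y = k1 + agg$y,
       cache = list(h = h, k1 = k1, qk = qk, a1p = a1p, a1 = a1, v = v,
                    p = agg$p, y2 = agg$y))
}

cotB <- function(cache, w, cfg, dy) {
  k <- cfg@cotKernel
  C <- dim(cache$h)[1]
  ab <- cotAggBackwardCpp(dy, cache$p, cache$v, cache$y2, k)
  vb <- convB(cache$h, w$v, ab$dv)
  a2b <- convB(cache$a1, w$attn2, ab$da)
  da1p <- a2b$dx * geluGradCpp(cache$a1p)
  a1b <- convB(cache$qk, w$attn1, da1p)
  dk1 <- dy + a1b$dx[seq_len(C), , , drop = FALSE]
  dh <- vb$dx + a1b$dx[C + seq_len(C), , , drop = FALSE]
  k1b <- convB(cache$h, w$k1, dk1, groups = cfg@cotGroups)
  list(dx = dh + k1b$dx,
       g = list(k1 = k1b$g, attn1 = a1b$g, attn2 = a2b$g, v = vb$g))
}

## -------------------------------------------------------- stage 2: round

roundF <- function(x, rw, cfg) {
  cs <- convStepF(x, rw, cfg)
  h <- cs$y
  if (dim(h)[2] < cfg@maxpoolSize) {
    stop("time length shorter than the pooling window; reduce rounds")
  }
  br <- NULL
  dafmCache <- cotCache <- NULL
  if (cfg@useDafm) {
    df <- dafmF(h, rw$dafm, cfg)
    br <- df$y
    dafmCache <- df$cache
  }
  if (cfg@useCot) {
    cf <- cotF(h, rw$cot, cfg)
    br <- if (is.null(br)) cf$y else br + cf$y
    cotCache <- cf$cache
  }
  if (is.null(br)) br <- h
  mp <- maxpoolForwardCpp(br, cfg@maxpoolSize)
  list(y = mp$y,
       cache = list(conv = cs$cache, dafm = dafmCache, cot = cotCache,
                    idx = mp$idx, tIn = dim(h)[2]))
}

roundB <- function(cache, rw, cfg, dy) {
  dbr <- maxpoolBackwardCpp(dy, cache$idx, cache$tIn)
  g <- list()
  dh <- NULL
  if (cfg@useDafm) {
    db <- dafmB(cache$dafm, rw$dafm, cfg, dbr)
    dh <- db$dx
    g$dafm <- db$g
  }
  if (cfg@useCot) {
    cb <- cotB(cache$cot, rw$cot, cfg, dbr)
    dh <- if (is.null(dh)) cb$dx else dh + cb$dx
    g$cot <- cb$g
  }
  if (is.null(dh)) dh <- dbr
  cs <- convStepB(cache$conv, rw, cfg, dh)
  ## weight order must mirror initParameters(): conv first, then branches
  list(dx = cs$dx, g = c(cs$g, g))
}

## ------------------------------------------------------------- classifier

clfF <- function(x, w) {
  C <- dim(x)[1]
  gap <- matrix(apply(x, 3, rowMeans), nrow = C)
  z1 <- w$fc1$w %*% gap + w$fc1$b
  a1 <- geluMat(z1)
  list(y = w$fc2$w %*% a1 + w$fc2$b,
       cache = list(gap = gap, z1 = z1, a1 = a1, tLen = dim(x)[2]))
}

clfB <- function(cache, w, ds) {
  da1 <- t(w$fc2$w) %*% ds
  dz1 <- da1 * geluGradMat(cache$z1)
  dgap <- t(w$fc1$w) %*% dz1
  C <- nrow(dgap); N <- ncol(dgap)
  dx <- aperm(array(dgap / cache$tLen, dim = c(C, N, cache$tLen)), c(1, 3, 2))
  list(dx = dx,
       g = list(fc1 = list(w = dz1 %*% t(cache$gap), b = rowSums(dz1)),
                fc2 = list(w = ds %*% t(cache$a1), b = rowSums(ds))))
}
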