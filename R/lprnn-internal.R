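# Internal machinery of the recurrent-convolutional residual denoiser:
# patch geometry (im2col index tables), forward and backward passes, the Adam
# optimizer and the optional least-squares patch critic. Everything operates
# on square patches flattened column-major to vectors on the [0, 1] intensity
# scale; feature maps are (pixels x channels) matrices.
#
# Convolutions use zero padding ("same" output size), the standard choice
# inside CNN denoisers; the classical filters in filters.R keep reflective
# borders.

denoiserGeometry <- function(config) {
  ps <- config@patchSize
  k <- config@convKernel
  s <- config@poolSize
  C <- config@featureChannels
  p <- (k - 1L) %/% 2L
  hp <- ps + 2L * p
  hw <- ps * ps
  ii <- rep(seq_len(ps), ps)
  jj <- rep(seq_len(ps), each = ps)
  k2 <- k * k
  NB <- matrix(0L, hw, k2)
  o <- 0L
  for (dv in (-p):p) {
    for (du in (-p):p) {
      o <- o + 1L
      NB[, o] <- (jj + p + dv - 1L) * hp + (ii + p + du)
    }
  }
  innerIdx <- (jj + p - 1L) * hp + (ii + p)
  # max-pool index table: one row per pooled cell, s^2 input pixels each
  n1 <- ps %/% s
  n2 <- n1 * n1
  ai <- rep(seq_len(n1), n1)
  bj <- rep(seq_len(n1), each = n1)
  poolIdx <- matrix(0L, n2, s * s)
  o <- 0L
  for (dv in 0:(s - 1L)) {
    for (du in 0:(s - 1L)) {
      o <- o + 1L
      poolIdx[, o] <- ((bj - 1L) * s + dv) * ps + (ai - 1L) * s + du + 1L
    }
  }
  # nearest-neighbour upsampling: input pixel -> pooled cell
  upMap <- (ceiling(jj / s) - 1L) * n1 + ceiling(ii / s)
  list(ps = ps, k = k, k2 = k2, C = C, s = s, hw = hw, padLen = hp * hp,
       NB = NB, innerIdx = innerIdx, n2 = n2, poolIdx = poolIdx,
       upMap = upMap, steps = config@recurrentSteps)
}

# x: vector length hw (one channel) -> hw x k2 patch-neighbourhood matrix
im2colVec <- function(x, geo) {
  pad <- numeric(geo$padLen)
  pad[geo$innerIdx] <- x
  res <- pad[geo$NB]
  dim(res) <- dim(geo$NB)
  res
}

# Zero-pad C feature maps into a (padLen x C) matrix.
padFeatures <- function(H, geo) {
  Hpad <- matrix(0, geo$padLen, geo$C)
  Hpad[geo$innerIdx, ] <- H
  Hpad
}

# Split the recurrent weight matrix ((k2*C) x C, rows grouped by input
# channel) into one C x C mixing matrix per kernel offset, for the
# shift-and-add convolution below.
splitOffsets <- function(Wr, geo) {
  base <- geo$k2 * (seq_len(geo$C) - 1L)
  lapply(seq_len(geo$k2), function(o) Wr[o + base, , drop = FALSE])
}

# C-in -> C-out "same" convolution as a sum over kernel offsets of a row
# gather followed by a small channel-mixing matmul; much faster in R than an
# explicit im2col of every step.
recurConv <- function(Hpad, WrO, geo) {
  out <- matrix(0, geo$hw, geo$C)
  for (o in seq_len(geo$k2)) {
    out <- out + Hpad[geo$NB[, o], , drop = FALSE] %*% WrO[[o]]
  }
  out
}

# Adjoint pair of recurConv: gradient wrt weights (accumulated into dWr) and
# wrt the un-padded input features.
recurConvBackward <- function(Hpad, WrO, dZ, dWr, geo) {
  base <- geo$k2 * (seq_len(geo$C) - 1L)
  gpad <- matrix(0, geo$padLen, geo$C)
  for (o in seq_len(geo$k2)) {
    idx <- geo$NB[, o]
    dWr[o + base, ] <- dWr[o + base, ] +
      crossprod(Hpad[idx, , drop = FALSE], dZ)
    gpad[idx, ] <- gpad[idx, , drop = FALSE] + tcrossprod(dZ, WrO[[o]])
  }
  list(dWr = dWr, dH = gpad[geo$innerIdx, , drop = FALSE])
}

addBias <- function(Z, b) Z + rep(b, each = nrow(Z))

# Forward pass over one flattened patch x (on [0, 1]). Returns the denoised
# patch and, when keepCache, every intermediate needed for backprop.
lprnnForward <- function(wts, geo, x, keepCache = FALSE) {
  cols0 <- im2colVec(x, geo)
  z1 <- addBias(cols0 %*% wts$W1, wts$b1)
  f0 <- pmax(z1, 0)
  # logical-pool branch: max-pool then nearest upsample, per channel
  n2 <- geo$n2
  s2 <- ncol(geo$poolIdx)
  pooled <- matrix(0, n2, geo$C)
  argRow <- matrix(0L, n2, geo$C)
  for (c in seq_len(geo$C)) {
    V <- f0[geo$poolIdx, c]
    dim(V) <- c(n2, s2)
    am <- max.col(V, ties.method = "first")
    pooled[, c] <- V[cbind(seq_len(n2), am)]
    argRow[, c] <- geo$poolIdx[cbind(seq_len(n2), am)]
  }
  pfeat <- pooled[geo$upMap, , drop = FALSE]
  # weight-shared recurrent refinement
  WrO <- splitOffsets(wts$Wr, geo)
  h <- f0
  padT <- if (keepCache) vector("list", geo$steps) else NULL
  maskT <- if (keepCache) vector("list", geo$steps) else NULL
  for (t in seq_len(geo$steps)) {
    Hpad <- padFeatures(h, geo)
    zt <- addBias(recurConv(Hpad, WrO, geo), wts$br) + pfeat
    h <- pmax(zt, 0)
    if (keepCache) {
      padT[[t]] <- Hpad
      maskT[[t]] <- zt > 0
    }
  }
  noise <- drop(h %*% wts$wOut) + wts$bOut
  out <- x - noise
  if (!keepCache) return(list(out = out))
  list(out = out, x = x, cols0 = cols0, mask1 = z1 > 0, f0 = f0,
       argRow = argRow, pfeat = pfeat, padT = padT, maskT = maskT,
       WrO = WrO, hT = h)
}

zeroGrads <- function(wts) lapply(wts, function(w) w * 0)

# Backward pass: dOut is dLoss/d(out) for one patch. Accumulates into grads.
lprnnBackward <- function(wts, geo, cache, dOut, grads) {
  dNoise <- -dOut
  grads$wOut <- grads$wOut + crossprod(cache$hT, dNoise)
  grads$bOut <- grads$bOut + sum(dNoise)
  dh <- dNoise %o% as.vector(wts$wOut)
  dPfeat <- matrix(0, geo$hw, geo$C)
  for (t in rev(seq_len(geo$steps))) {
    dZt <- dh * cache$maskT[[t]]
    grads$br <- grads$br + colSums(dZt)
    dPfeat <- dPfeat + dZt
    bk <- recurConvBackward(cache$padT[[t]], cache$WrO, dZt, grads$Wr, geo)
    grads$Wr <- bk$dWr
    dh <- bk$dH
  }
  # pooled branch: upsample adjoint is a sum over each pooled cell, then the
  # gradient routes to the argmax pixel of that cell
  dPooled <- rowsum(dPfeat, geo$upMap)
  dF0 <- dh
  for (c in seq_len(geo$C)) {
    sel <- cbind(cache$argRow[, c], c)
    dF0[sel] <- dF0[sel] + dPooled[, c]
  }
  dZ1 <- dF0 * cache$mask1
  grads$W1 <- grads$W1 + crossprod(cache$cols0, dZ1)
  grads$b1 <- grads$b1 + colSums(dZ1)
  grads
}

# Loss value and gradient wrt the network output, for one flattened patch on
# the [0, 1] scale. The adversarial contribution is handled by the caller.
patchLossGrad <- function(out, target, ps, lossWeights) {
  diff <- out - target
  hw <- length(out)
  loss <- lossWeights@l1Weight * mean(abs(diff))
  g <- lossWeights@l1Weight * sign(diff) / hw
  if (lossWeights@edgeWeight > 0) {
    O <- matrix(out, ps, ps)
    Tm <- matrix(target, ps, ps)
    dv <- (O[2:ps, , drop = FALSE] - O[1:(ps - 1), , drop = FALSE]) -
      (Tm[2:ps, , drop = FALSE] - Tm[1:(ps - 1), , drop = FALSE])
    M <- (ps - 1L) * ps
    loss <- loss + lossWeights@edgeWeight * sum(abs(dv)) / M
    s <- sign(dv)
    ge <- matrix(0, ps, ps)
    ge[2:ps, ] <- ge[2:ps, ] + s
    ge[1:(ps - 1), ] <- ge[1:(ps - 1), ] - s
    g <- g + lossWeights@edgeWeight * as.vector(ge) / M
  }
  list(loss = loss, grad = g)
}

# --- Adam -------------------------------------------------------------------

adamInit <- function(wts) {
  list(m = zeroGrads(wts), v = zeroGrads(wts), t = 0L)
}

adamStep <- function(wts, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(wts)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    wts[[nm]] <- wts[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(wts = wts, state = state)
}

# --- least-squares patch critic (used only when advWeight > 0) -------------

criticInit <- function(hw, seed) {
  withr::with_seed(seed, {
    list(A1 = matrix(stats::rnorm(hw * 32L, sd = sqrt(2 / hw)), hw, 32L),
         c1 = numeric(32L),
         A2 = matrix(stats::rnorm(32L * 16L, sd = sqrt(2 / 32)), 32L, 16L),
         c2 = numeric(16L),
         a3 = matrix(stats::rnorm(16L, sd = sqrt(2 / 16)), 16L, 1L),
         c3 = 0)
  })
}

criticForward <- function(cw, x) {
  z1 <- drop(crossprod(cw$A1, x)) + cw$c1
  h1 <- pmax(z1, 0)
  z2 <- drop(crossprod(cw$A2, h1)) + cw$c2
  h2 <- pmax(z2, 0)
  score <- drop(crossprod(cw$a3, h2)) + cw$c3
  list(score = score, x = x, m1 = z1 > 0, h1 = h1, m2 = z2 > 0, h2 = h2)
}

# dScore: dLoss/dScore (scalar). Returns weight grads and dLoss/dx.
criticBackward <- function(cw, cache, dScore) {
  dh2 <- drop(cw$a3) * dScore
  dz2 <- dh2 * cache$m2
  dh1 <- drop(cw$A2 %*% dz2)
  dz1 <- dh1 * cache$m1
  list(grads = list(A1 = cache$x %o% dz1, c1 = dz1,
                    A2 = cache$h1 %o% dz2, c2 = dz2,
                    a3 = matrix(cache$h2 * dScore, ncol = 1L), c3 = dScore),
       dx = drop(cw$A1 %*% dz1))
}
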