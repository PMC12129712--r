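# Reverse-mode layers for the drug-cell interaction network.
#
# Convolutional activations are stored as dense matrices M[r, c] with
# row index r = (b - 1) * S + s, where s is a column-major spatial index
# over the (P, G) grid (pathway index fastest), b the batch index, and c
# the channel.  This keeps every layer a plain matrix op (BLAS matmul,
# colMeans, gathers with precomputed integer maps) with no per-channel
# loops in the hot path.  Every forward returns list(out=, cache=); every
# backward consumes the cache plus the upstream gradient.  All backwards
# are validated by finite differences in the test suite.

# --- index maps ------------------------------------------------------------

# Base im2col map for a (P, G) grid, C input channels, odd kernel k with
# zero "same" padding: an (S x C*k*k) matrix of indices into the
# flattened (s, c) input plane (s fastest), 0 marking out-of-grid taps.
conv_index_map <- function(P, G, C, k) {
  stopifnot(k %% 2 == 1)
  S <- P * G
  r <- (k - 1L) / 2L
  pos_p <- rep(seq_len(P), times = G)
  pos_g <- rep(seq_len(G), each = P)
  offs <- expand.grid(dp = -r:r, dg = -r:r)
  idx <- matrix(0L, S, C * k * k)
  col <- 0L
  for (ci in seq_len(C)) {
    for (o in seq_len(nrow(offs))) {
      col <- col + 1L
      pp <- pos_p + offs$dp[o]
      gg <- pos_g + offs$dg[o]
      ok <- pp >= 1L & pp <= P & gg >= 1L & gg <= G
      id <- integer(S)
      id[ok] <- pp[ok] + (gg[ok] - 1L) * P + (ci - 1L) * S
      idx[, col] <- id
    }
  }
  idx
}

# Expand a base map to batch size B: indices into as.vector of the
# (S*B x C) activation matrix, shifted by +1 so that 1 addresses a
# prepended zero (padding) element.
conv_batch_map <- function(idxmat, S, B) {
  Ckk <- ncol(idxmat)
  sN <- ((idxmat - 1L) %% S) + 1L
  cN <- (idxmat - 1L) %/% S
  big <- matrix(1L, S * B, Ckk)
  boff <- (seq_len(B) - 1L) * S
  for (t in seq_len(Ckk)) {
    col <- outer(sN[, t], boff, "+") + cN[, t] * (S * B)
    col[idxmat[, t] == 0L, ] <- 0L
    big[, t] <- as.vector(col) + 1L
  }
  big
}

# Pooling map: for each pooled cell (size^2 taps), source spatial indices
# (0 = off grid when P or G is odd).
pool_index_map <- function(P, G, size = 2L) {
  P2 <- ceiling(P / size); G2 <- ceiling(G / size)
  S2 <- P2 * G2
  idx <- matrix(0L, S2, size * size)
  cell <- 0L
  for (g2 in seq_len(G2)) for (p2 in seq_len(P2)) {
    cell <- cell + 1L
    tap <- 0L
    for (dg in seq_len(size)) for (dp in seq_len(size)) {
      tap <- tap + 1L
      p <- (p2 - 1L) * size + dp
      g <- (g2 - 1L) * size + dg
      if (p <= P && g <= G) idx[cell, tap] <- p + (g - 1L) * P
    }
  }
  list(idx = idx, P2 = P2, G2 = G2)
}

# Row-index expansion of the pool map to batch size B (0 = off grid).
pool_batch_map <- function(pidx, S, B) {
  idx <- pidx$idx
  S2 <- nrow(idx)
  boff <- (seq_len(B) - 1L) * S
  out <- matrix(0L, S2 * B, ncol(idx))
  for (t in seq_len(ncol(idx))) {
    col <- outer(idx[, t], boff, "+")
    col[idx[, t] == 0L, ] <- 0L
    out[, t] <- as.vector(col)
  }
  out
}

# Permutation turning as.vector of an (S*B x C) matrix (s, b, c order)
# into (s, c, b) order, for flattening into per-sample vectors.
flatten_perm <- function(S, B, C) {
  # target position (s, c, b) reads source (s, b, c)
  s <- rep(seq_len(S), times = C * B)
  c <- rep(rep(seq_len(C), each = S), times = B)
  b <- rep(seq_len(B), each = S * C)
  (c - 1L) * (S * B) + (b - 1L) * S + s
}

# --- 2-d convolution (same padding) ---------------------------------------

conv2d_forward <- function(M, W, b, bigidx, bigidx_back = NULL) {
  Mpad <- c(0, M)
  Pm <- Mpad[bigidx]
  dim(Pm) <- dim(bigidx)
  Y <- Pm %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(out = Y, cache = list(Pm = Pm, W = W, n_in_ch = ncol(M),
                             bigidx_back = bigidx_back))
}

# The input gradient of a zero-padded convolution is itself a
# convolution of the output gradient with the spatially flipped,
# channel-transposed kernel; bigidx_back is the im2col map over the
# output-channel plane.
conv2d_backward <- function(dY, cache) {
  dW <- crossprod(cache$Pm, dY)
  db <- colSums(dY)
  W <- cache$W
  Cout <- ncol(W)
  Cin <- cache$n_in_ch
  kk <- nrow(W) / Cin
  Wa <- array(W, c(kk, Cin, Cout))
  Wback <- matrix(aperm(Wa[kk:1, , , drop = FALSE], c(1, 3, 2)),
                  kk * Cout, Cin)
  dYpad <- c(0, dY)
  Pb <- dYpad[cache$bigidx_back]
  dim(Pb) <- dim(cache$bigidx_back)
  list(dM = Pb %*% Wback, dW = dW, db = db)
}

# --- batch normalisation (per channel over spatial x batch) ---------------

bn_forward <- function(M, gamma, beta, running, training, momentum = 0.1,
                       eps = 1e-5) {
  m <- nrow(M)
  if (training) {
    mu <- colMeans(M)
    xc <- M - rep(mu, each = m)
    v <- colMeans(xc * xc)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
    xc <- M - rep(mu, each = m)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(invstd, each = m)
  out <- xhat * rep(gamma, each = m) + rep(beta, each = m)
  list(out = out,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma),
       running = running)
}

bn_backward <- function(dY, cache) {
  m <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dM <- rep(cache$gamma * cache$invstd, each = m) *
    (dY - rep(dbeta / m, each = m) - xhat * rep(dgamma / m, each = m))
  list(dM = dM, dgamma = dgamma, dbeta = dbeta)
}

# --- ReLU ------------------------------------------------------------------

relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}

relu_backward <- function(dY, mask) dY * mask

# --- max pooling -----------------------------------------------------------

maxpool_forward <- function(M, bigpool) {
  ncols <- ncol(M)
  best <- matrix(-Inf, nrow(bigpool), ncols)
  amax <- matrix(0L, nrow(bigpool), ncols)
  for (j in seq_len(ncol(bigpool))) {
    src <- bigpool[, j]
    off <- src == 0L
    Vj <- M[pmax(src, 1L), , drop = FALSE]
    if (any(off)) Vj[off, ] <- -Inf
    upd <- Vj > best
    best[upd] <- Vj[upd]
    amax[upd] <- j
  }
  list(out = best,
       cache = list(amax = amax, bigpool = bigpool, n_in = nrow(M)))
}

maxpool_backward <- function(dY, cache) {
  dM <- matrix(0, cache$n_in, ncol(dY))
  for (j in seq_len(ncol(cache$bigpool))) {
    src <- cache$bigpool[, j]
    sel <- which(src > 0L)
    if (!length(sel)) next
    contrib <- dY[sel, , drop = FALSE] *
      (cache$amax[sel, , drop = FALSE] == j)
    dM[src[sel], ] <- dM[src[sel], ] + contrib
  }
  dM
}

# --- flatten (S2*B x C) -> (B x S2*C) --------------------------------------

flatten_forward <- function(M, perm, B) {
  v <- as.vector(M)[perm]
  list(out = t(matrix(v, length(v) / B, B)),
       cache = list(perm = perm, d = dim(M)))
}

flatten_backward <- function(dY, cache) {
  v <- as.vector(t(dY))
  out <- numeric(length(v))
  out[cache$perm] <- v
  matrix(out, cache$d[1], cache$d[2])
}

# --- dense layer -----------------------------------------------------------

linear_forward <- function(X, W, b) {
  Y <- X %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(out = Y, cache = list(X = X, W = W))
}

linear_backward <- function(dY, cache) {
  list(dX = dY %*% t(cache$W),
       dW = crossprod(cache$X, dY),
       db = colSums(dY))
}
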