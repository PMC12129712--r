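#' @include AllClasses.R nn-layers.R
NULL

#' Resolve a model configuration
#'
#' Fills in architecture defaults for the drug-cell interaction network:
#' a stacked large-kernel CNN over the 3-channel pathway-by-gene grid
#' (Conv-BN-ReLU twice, 2x2 max pool, linear head to `d1`), an MLP drug
#' encoder over the 2048-bit fingerprint (hidden widths `mlp_hidden`,
#' output `d2`), and multi-head cross-modal attention in which, by
#' default, the Query is derived from the drug representation and Key and
#' Value from the cell representation.  Embeddings are reshaped into
#' `tokens_per_modality` tokens each so the attention is non-degenerate.
#'
#' @param channels number of omics channels (3 for CNV+MRNA+METH).
#' @param P number of pathways (grid height).
#' @param G padded gene-slot count (grid width).
#' @param kernel_size odd convolution kernel size; 25 reproduces the
#'   reference architecture, 3 is a sensible desk-scale choice.
#' @param conv_channels integer vector of the two conv layer widths.
#' @param pool max-pool window (default 2).
#' @param d1 cell embedding width.
#' @param fp_bits fingerprint width (default 2048).
#' @param mlp_hidden integer vector of MLP hidden widths (default 512).
#' @param d2 drug embedding width.
#' @param latent_dim attention model width; must be divisible by `heads`.
#' @param heads number of attention heads.
#' @param tokens_per_modality token count T; `d1` and `d2` must be
#'   divisible by T.
#' @param attention_direction `"drug_query"` (default: Q from drugs, K/V
#'   from cells) or `"cell_query"` (the transposed reading).
#' @return named list, the resolved configuration.
#' @export
modinConfig <- function(channels = 3L, P, G, kernel_size = 25L,
                        conv_channels = c(32L, 32L), pool = 2L,
                        d1 = 512L, fp_bits = 2048L, mlp_hidden = 512L,
                        d2 = 512L, latent_dim = 256L, heads = 8L,
                        tokens_per_modality = 4L,
                        attention_direction = c("drug_query", "cell_query")) {
  attention_direction <- match.arg(attention_direction)
  stopifnot(kernel_size %% 2 == 1, length(conv_channels) == 2,
            latent_dim %% heads == 0,
            d1 %% tokens_per_modality == 0,
            d2 %% tokens_per_modality == 0)
  P2 <- ceiling(P / pool); G2 <- ceiling(G / pool)
  if (P2 < 1 || G2 < 1)
    stop("grid ", P, "x", G, " collapses below 1x1 after pooling (",
         P2, "x", G2, ")")
  list(channels = as.integer(channels), P = as.integer(P), G = as.integer(G),
       kernel_size = as.integer(kernel_size),
       conv_channels = as.integer(conv_channels), pool = as.integer(pool),
       d1 = as.integer(d1), fp_bits = as.integer(fp_bits),
       mlp_hidden = as.integer(mlp_hidden), d2 = as.integer(d2),
       latent_dim = as.integer(latent_dim), heads = as.integer(heads),
       tokens_per_modality = as.integer(tokens_per_modality),
       attention_direction = attention_direction,
       flat_dim = as.integer(P2 * G2 * conv_channels[2]))
}

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

xavier_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(1 / nin)), nin, nout)
}

#' Initialise a ModinModel
#'
#' Draws all weights from He/Xavier-scaled normals under the given seed;
#' biases start at zero, batch-norm scale at one.
#'
#' @param config resolved configuration from [modinConfig()].
#' @param seed integer RNG seed for the initial weights.
#' @return an untrained [ModinModel-class].
#' @export
modinInit <- function(config, seed = 1L) {
  set.seed(seed)
  k <- config$kernel_size
  C <- config$channels
  c1 <- config$conv_channels[1]; c2 <- config$conv_channels[2]
  params <- list(
    conv1 = list(W = he_init(C * k * k, c1), b = numeric(c1)),
    bn1 = list(gamma = rep(1, c1), beta = numeric(c1)),
    conv2 = list(W = he_init(c1 * k * k, c2), b = numeric(c2)),
    bn2 = list(gamma = rep(1, c2), beta = numeric(c2)),
    fc = list(W = he_init(config$flat_dim, config$d1),
              b = numeric(config$d1)),
    att = list(
      Wk = xavier_init(config$d1 %/% config$tokens_per_modality,
                       config$latent_dim),
      bk = numeric(config$latent_dim),
      Wv = xavier_init(config$d1 %/% config$tokens_per_modality,
                       config$latent_dim),
      bv = numeric(config$latent_dim),
      Wq = xavier_init(config$d2 %/% config$tokens_per_modality,
                       config$latent_dim),
      bq = numeric(config$latent_dim),
      Wy = xavier_init(config$tokens_per_modality * config$latent_dim, 1L),
      by = 0))
  widths <- c(config$fp_bits, config$mlp_hidden, config$d2)
  mlp <- list()
  for (l in seq_len(length(widths) - 1L)) {
    mlp[[l]] <- list(W = he_init(widths[l], widths[l + 1L]),
                     b = numeric(widths[l + 1L]))
  }
  params$mlp <- mlp
  if (config$attention_direction == "cell_query") {
    # swap projection input widths: Q reads cell tokens, K/V drug tokens
    wq <- config$d1 %/% config$tokens_per_modality
    wkv <- config$d2 %/% config$tokens_per_modality
    params$att$Wk <- xavier_init(wkv, config$latent_dim)
    params$att$Wv <- xavier_init(wkv, config$latent_dim)
    params$att$Wq <- xavier_init(wq, config$latent_dim)
  }
  buffers <- list(
    bn1 = list(mean = numeric(c1), var = rep(1, c1)),
    bn2 = list(mean = numeric(c2), var = rep(1, c2)))
  new("ModinModel", config = config, params = params, buffers = buffers,
      trained = FALSE)
}

# reshape (B x d) embedding into (B*T x w) token matrix, token-major rows
tokenize <- function(H, T) {
  B <- nrow(H); w <- ncol(H) %/% T
  M <- matrix(0, B * T, w)
  for (t in seq_len(T))
    M[(t - 1L) * B + seq_len(B), ] <- H[, (t - 1L) * w + seq_len(w)]
  M
}

untokenize <- function(M, T, B) {
  w <- ncol(M)
  H <- matrix(0, B, T * w)
  for (t in seq_len(T))
    H[, (t - 1L) * w + seq_len(w)] <- M[(t - 1L) * B + seq_len(B), ]
  H
}

# Multi-head scaled dot-product attention between token sets.
# Qm, Km, Vm: (B*T x L) token-major matrices.  Returns the (B x T*L)
# flattened head-concatenated output plus caches for backward.
mha_forward <- function(Qm, Km, Vm, heads, T, B) {
  L <- ncol(Qm)
  dk <- L %/% heads
  scale <- 1 / sqrt(dk)
  Smax <- vector("list", heads)
  Ofl <- matrix(0, B, T * L)
  for (h in seq_len(heads)) {
    hc <- (h - 1L) * dk + seq_len(dk)
    Sh <- array(0, c(B, T, T))
    for (i in seq_len(T)) {
      Qi <- Qm[(i - 1L) * B + seq_len(B), hc, drop = FALSE]
      logits <- matrix(0, B, T)
      for (j in seq_len(T)) {
        Kj <- Km[(j - 1L) * B + seq_len(B), hc, drop = FALSE]
        logits[, j] <- rowSums(Qi * Kj) * scale
      }
      if (anyNA(logits))
        stop("NaN in attention logits (query token ", i, ")")
      m <- apply(logits, 1L, max)
      e <- exp(logits - m)
      Sh[, i, ] <- e / rowSums(e)
      Oi <- matrix(0, B, dk)
      for (j in seq_len(T)) {
        Vj <- Vm[(j - 1L) * B + seq_len(B), hc, drop = FALSE]
        Oi <- Oi + Sh[, i, j] * Vj
      }
      Ofl[, (i - 1L) * L + hc] <- Oi
    }
    Smax[[h]] <- Sh
  }
  list(out = Ofl, cache = list(Qm = Qm, Km = Km, Vm = Vm, Smax = Smax,
                               heads = heads, T = T, B = B, dk = dk))
}

mha_backward <- function(dOfl, cache) {
  heads <- cache$heads; T <- cache$T; B <- cache$B; dk <- cache$dk
  L <- heads * dk
  scale <- 1 / sqrt(dk)
  dQ <- matrix(0, B * T, L); dK <- dQ; dV <- dQ
  for (h in seq_len(heads)) {
    hc <- (h - 1L) * dk + seq_len(dk)
    Sh <- cache$Smax[[h]]
    for (i in seq_len(T)) {
      ri <- (i - 1L) * B + seq_len(B)
      dOi <- dOfl[, (i - 1L) * L + hc, drop = FALSE]
      dS <- matrix(0, B, T)
      for (j in seq_len(T)) {
        Vj <- cache$Vm[(j - 1L) * B + seq_len(B), hc, drop = FALSE]
        dS[, j] <- rowSums(dOi * Vj)
        dV[(j - 1L) * B + seq_len(B), hc] <-
          dV[(j - 1L) * B + seq_len(B), hc] + Sh[, i, j] * dOi
      }
      Si <- Sh[, i, , drop = TRUE]
      if (is.null(dim(Si))) Si <- matrix(Si, B, T)
      dLog <- Si * (dS - rowSums(Si * dS))
      Qi <- cache$Qm[ri, hc, drop = FALSE]
      for (j in seq_len(T)) {
        rj <- (j - 1L) * B + seq_len(B)
        Kj <- cache$Km[rj, hc, drop = FALSE]
        dQ[ri, hc] <- dQ[ri, hc] + dLog[, j] * Kj * scale
        dK[rj, hc] <- dK[rj, hc] + dLog[, j] * Qi * scale
      }
    }
  }
  list(dQ = dQ, dK = dK, dV = dV)
}

# Full forward pass.  grids: (B, C, P, G) array; fps: (B, fp_bits);
# pad_s: spatial indices of padded gene slots (activations there are
# re-zeroed between layers so padding stays inert through the stack).
# Returns list(y=, cache=) in training mode, or just predictions in eval.
modin_forward <- function(model, grids, fps, training = FALSE,
                          maps = NULL, pad_s = integer(0)) {
  cfg <- model$config
  p <- model$params
  buf <- model$buffers
  B <- dim(grids)[1]
  S <- cfg$P * cfg$G
  if (is.null(maps)) maps <- modin_maps(cfg)
  bm <- maps_for_batch(maps, cfg, B)
  pad_rows <- if (length(pad_s))
    as.vector(outer(pad_s, (seq_len(B) - 1L) * S, "+")) else integer(0)
  # rows (b-1)*S + s, columns channels
  A0 <- matrix(aperm(grids, c(3, 4, 1, 2)), S * B, cfg$channels)

  cv1 <- conv2d_forward(A0, p$conv1$W, p$conv1$b, bm$conv1, bm$conv1_back)
  bn1 <- bn_forward(cv1$out, p$bn1$gamma, p$bn1$beta, buf$bn1, training)
  r1 <- relu_forward(bn1$out)
  if (length(pad_rows)) r1$out[pad_rows, ] <- 0
  cv2 <- conv2d_forward(r1$out, p$conv2$W, p$conv2$b, bm$conv2,
                        bm$conv2_back)
  bn2 <- bn_forward(cv2$out, p$bn2$gamma, p$bn2$beta, buf$bn2, training)
  r2 <- relu_forward(bn2$out)
  if (length(pad_rows)) r2$out[pad_rows, ] <- 0
  pl <- maxpool_forward(r2$out, bm$pool)
  fl <- flatten_forward(pl$out, bm$perm, B)
  fc <- linear_forward(fl$out, p$fc$W, p$fc$b)
  Hc <- fc$out                                            # (B, d1)

  X <- fps
  mlp_caches <- vector("list", length(p$mlp))
  relu_masks <- vector("list", length(p$mlp))
  for (l in seq_along(p$mlp)) {
    lin <- linear_forward(X, p$mlp[[l]]$W, p$mlp[[l]]$b)
    mlp_caches[[l]] <- lin$cache
    if (l < length(p$mlp)) {
      rl <- relu_forward(lin$out)
      relu_masks[[l]] <- rl$cache
      X <- rl$out
    } else X <- lin$out
  }
  Hd <- X                                                 # (B, d2)

  T <- cfg$tokens_per_modality
  Mc <- tokenize(Hc, T)
  Md <- tokenize(Hd, T)
  if (cfg$attention_direction == "drug_query") {
    Kin <- Mc; Vin <- Mc; Qin <- Md
  } else {
    Kin <- Md; Vin <- Md; Qin <- Mc
  }
  Kl <- linear_forward(Kin, p$att$Wk, p$att$bk)
  Vl <- linear_forward(Vin, p$att$Wv, p$att$bv)
  Ql <- linear_forward(Qin, p$att$Wq, p$att$bq)
  mh <- mha_forward(Ql$out, Kl$out, Vl$out, cfg$heads, T, B)
  yl <- linear_forward(mh$out, p$att$Wy, matrix(p$att$by, 1))
  y <- as.numeric(yl$out)

  if (training) {
    model$buffers$bn1 <- bn1$running
    model$buffers$bn2 <- bn2$running
  }
  list(y = y, buffers = model$buffers, Hc = Hc, Hd = Hd,
       cache = if (training) list(
         cv1 = cv1$cache, bn1 = bn1$cache, r1 = r1$cache,
         cv2 = cv2$cache, bn2 = bn2$cache, r2 = r2$cache,
         pl = pl$cache, fl = fl$cache, fc = fc$cache,
         mlp = mlp_caches, relu_masks = relu_masks,
         Kl = Kl$cache, Vl = Vl$cache, Ql = Ql$cache, mh = mh$cache,
         yl = yl$cache, B = B, T = T, pad_rows = pad_rows) else NULL)
}

# Backward pass from d(loss)/d(y); returns gradient list shaped like params.
modin_backward <- function(model, cache, dy) {
  cfg <- model$config
  p <- model$params
  g <- rapply(p, function(x) x * 0, how = "replace")
  B <- cache$B; T <- cache$T

  dyl <- linear_backward(matrix(dy, ncol = 1L), cache$yl)
  g$att$Wy <- dyl$dW
  g$att$by <- dyl$db
  dmh <- mha_backward(dyl$dX, cache$mh)
  dKl <- linear_backward(dmh$dK, cache$Kl)
  dVl <- linear_backward(dmh$dV, cache$Vl)
  dQl <- linear_backward(dmh$dQ, cache$Ql)
  g$att$Wk <- dKl$dW; g$att$bk <- dKl$db
  g$att$Wv <- dVl$dW; g$att$bv <- dVl$db
  g$att$Wq <- dQl$dW; g$att$bq <- dQl$db
  if (cfg$attention_direction == "drug_query") {
    dMc <- dKl$dX + dVl$dX
    dMd <- dQl$dX
  } else {
    dMd <- dKl$dX + dVl$dX
    dMc <- dQl$dX
  }
  dHc <- untokenize(dMc, T, B)
  dHd <- untokenize(dMd, T, B)

  dX <- dHd
  for (l in rev(seq_along(p$mlp))) {
    if (l < length(p$mlp)) dX <- relu_backward(dX, cache$relu_masks[[l]])
    lb <- linear_backward(dX, cache$mlp[[l]])
    g$mlp[[l]]$W <- lb$dW
    g$mlp[[l]]$b <- lb$db
    dX <- lb$dX
  }

  dfc <- linear_backward(dHc, cache$fc)
  g$fc$W <- dfc$dW; g$fc$b <- dfc$db
  dfl <- flatten_backward(dfc$dX, cache$fl)
  dpl <- maxpool_backward(dfl, cache$pl)
  if (length(cache$pad_rows)) dpl[cache$pad_rows, ] <- 0
  dr2 <- relu_backward(dpl, cache$r2)
  dbn2 <- bn_backward(dr2, cache$bn2)
  g$bn2$gamma <- dbn2$dgamma; g$bn2$beta <- dbn2$dbeta
  dcv2 <- conv2d_backward(dbn2$dM, cache$cv2)
  g$conv2$W <- dcv2$dW; g$conv2$b <- dcv2$db
  if (length(cache$pad_rows)) dcv2$dM[cache$pad_rows, ] <- 0
  dr1 <- relu_backward(dcv2$dM, cache$r1)
  dbn1 <- bn_backward(dr1, cache$bn1)
  g$bn1$gamma <- dbn1$dgamma; g$bn1$beta <- dbn1$dbeta
  dcv1 <- conv2d_backward(dbn1$dM, cache$cv1)
  g$conv1$W <- dcv1$dW; g$conv1$b <- dcv1$db
  g
}

# Precompute convolution / pooling index maps for a configuration.
# Batch-size-dependent expansions are cached inside the returned
# environment, so repeated minibatches of the same size pay nothing.
modin_maps <- function(cfg) {
  e <- new.env(parent = emptyenv())
  k <- cfg$kernel_size
  e$conv1 <- conv_index_map(cfg$P, cfg$G, cfg$channels, k)
  e$conv2 <- conv_index_map(cfg$P, cfg$G, cfg$conv_channels[1], k)
  e$conv2_back <- conv_index_map(cfg$P, cfg$G, cfg$conv_channels[2], k)
  e$pool <- pool_index_map(cfg$P, cfg$G, cfg$pool)
  e$batch <- list()
  e
}

maps_for_batch <- function(maps, cfg, B) {
  key <- as.character(B)
  bm <- maps$batch[[key]]
  if (is.null(bm)) {
    S <- cfg$P * cfg$G
    S2 <- maps$pool$P2 * maps$pool$G2
    conv2 <- conv_batch_map(maps$conv2, S, B)
    bm <- list(conv1 = conv_batch_map(maps$conv1, S, B),
               conv2 = conv2,
               conv1_back = conv2,   # conv1's output plane = conv2's input
               conv2_back = if (identical(cfg$conv_channels[1],
                                          cfg$conv_channels[2])) conv2
                            else conv_batch_map(maps$conv2_back, S, B),
               pool = pool_batch_map(maps$pool, S, B),
               perm = flatten_perm(S2, B, cfg$conv_channels[2]))
    maps$batch[[key]] <- bm
  }
  bm
}

# Internal list view of a ModinModel (forward/backward work on lists so
# buffers can be updated without S4 slot churn inside the hot loop).
model_as_list <- function(object) {
  list(config = object@config, params = object@params,
       buffers = object@buffers)
}
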