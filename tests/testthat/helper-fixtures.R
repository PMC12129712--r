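# Shared fixtures, built in code at test time.

# Tiny three-modality omics set with a controllable gene universe.
tiny_omics <- function(n = 4, genes = paste0("g", 1:6), seed = 1) {
  set.seed(seed)
  samples <- paste0("s", seq_len(n))
  mk <- function(mod, gen) {
    v <- matrix(round(rnorm(n * length(gen)), 3), n, length(gen),
                dimnames = list(samples, gen))
    OmicsMatrix(v, mod)
  }
  list(CNV = mk("CNV", genes), MRNA = mk("MRNA", genes),
       METH = mk("METH", genes))
}

tiny_pmap <- function() {
  PathwayGeneMap(list(pwA = c("g1", "g2"), pwB = c("g3", "g4", "g5")))
}

# Desk-scale model configuration used across the network tests.
tiny_config <- function(channels = 2, P = 3, G = 4, d1 = 8, d2 = 8,
                        fp_bits = 16, latent = 4, heads = 2, tokens = 2) {
  modinConfig(channels = channels, P = P, G = G, kernel_size = 3,
              conv_channels = c(2, 2), pool = 2, d1 = d1,
              fp_bits = fp_bits, mlp_hidden = 8, d2 = d2,
              latent_dim = latent, heads = heads,
              tokens_per_modality = tokens)
}

# Naive sliding-window convolution with zero "same" padding: the
# independent oracle for the im2col implementation.  x: (C, P, G) array,
# W: (Cin*k*k x Cout) in the package's (offset fastest, channel outer)
# column layout, b: length-Cout bias.
naive_conv2d <- function(x, W, b, k) {
  C <- dim(x)[1]; P <- dim(x)[2]; G <- dim(x)[3]
  Cout <- ncol(W)
  r <- (k - 1) / 2
  offs <- expand.grid(dp = -r:r, dg = -r:r)
  out <- array(0, c(Cout, P, G))
  for (co in seq_len(Cout)) {
    for (p in seq_len(P)) for (g in seq_len(G)) {
      acc <- b[co]
      for (ci in seq_len(C)) for (o in seq_len(nrow(offs))) {
        pp <- p + offs$dp[o]; gg <- g + offs$dg[o]
        xv <- if (pp >= 1 && pp <= P && gg >= 1 && gg <= G)
          x[ci, pp, gg] else 0
        acc <- acc + xv * W[(ci - 1) * k * k + o, co]
      }
      out[co, p, g] <- acc
    }
  }
  out
}

# Loop-based scaled dot-product attention oracle: q, k, v are (T x dk)
# matrices for one head of one sample.
naive_attention_head <- function(q, k, v) {
  dk <- ncol(q)
  out <- matrix(0, nrow(q), dk)
  for (i in seq_len(nrow(q))) {
    logits <- numeric(nrow(k))
    for (j in seq_len(nrow(k))) logits[j] <- sum(q[i, ] * k[j, ]) / sqrt(dk)
    w <- exp(logits - max(logits))
    w <- w / sum(w)
    for (j in seq_len(nrow(k))) out[i, ] <- out[i, ] + w[j] * v[j, ]
  }
  out
}

# Brute-force two-sample KS statistic: maximum ECDF gap over the pooled
# sample points.
naive_ks_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# The desk-scale planted-response fixture shared by the recovery and
# ablation checks (30 cells x 80 drugs, attainable R^2 0.9).
recovery_fixture <- function(seed = 11) {
  spec <- simulationSpec(n_cells = 30, n_genes = 300, n_pathways = 8,
                         pathway_size_range = c(6, 12), n_drugs = 80,
                         target_r2 = 0.9, effect_channel = "MRNA",
                         seed = seed)
  sim <- simulateOmics(spec)
  drugs <- simulateDrugs(spec)
  resp <- simulateResponses(sim, drugs, spec)
  G <- max(lengths(pathwayMembers(sim$pathways)))
  cfg_fn <- function(channels)
    modinConfig(channels = channels, P = 8, G = G, kernel_size = 3,
                conv_channels = c(8, 8), d1 = 64, mlp_hidden = 64,
                d2 = 64, latent_dim = 32, heads = 4,
                tokens_per_modality = 4)
  list(spec = spec, sim = sim, drugs = drugs, resp = resp, cfg_fn = cfg_fn)
}
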