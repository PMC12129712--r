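# The convolution, pooling and full-network backward passes are checked
# against independent naive oracles and finite differences.

test_that("im2col convolution matches a nested-loop sliding-window oracle", {
  set.seed(21)
  C <- 2; P <- 4; G <- 6; k <- 3; Cout <- 3; B <- 2
  W <- matrix(round(rnorm(C * k * k * Cout), 2), C * k * k, Cout)
  b <- c(0.1, -0.5, 0.2)
  x <- array(round(rnorm(B * C * P * G), 2), c(B, C, P, G))

  S <- P * G
  base <- modin:::conv_index_map(P, G, C, k)
  bigidx <- modin:::conv_batch_map(base, S, B)
  M <- matrix(aperm(x, c(3, 4, 1, 2)), S * B, C)
  out <- modin:::conv2d_forward(M, W, b, bigidx)$out

  for (bb in seq_len(B)) {
    oracle <- naive_conv2d(x[bb, , , ], W, b, k)
    for (co in seq_len(Cout)) for (p in seq_len(P)) for (g in seq_len(G)) {
      s <- p + (g - 1) * P
      expect_equal(out[(bb - 1) * S + s, co], oracle[co, p, g],
                   tolerance = 1e-10)
    }
  }
})

test_that("max pooling picks window maxima, including odd-sized edges", {
  P <- 3; G <- 5; B <- 1
  x <- matrix(seq_len(P * G), P, G)         # distinct values
  M <- matrix(as.vector(x), P * G, 1)
  pidx <- modin:::pool_index_map(P, G, 2L)
  bp <- modin:::pool_batch_map(pidx, P * G, B)
  out <- modin:::maxpool_forward(M, bp)$out
  # oracle: loop over 2x2 windows
  for (p2 in 1:2) for (g2 in 1:3) {
    rows <- ((p2 - 1) * 2 + 1):min(p2 * 2, P)
    cols <- ((g2 - 1) * 2 + 1):min(g2 * 2, G)
    s2 <- p2 + (g2 - 1) * 2
    expect_equal(out[s2, 1], max(x[rows, cols]))
  }
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(7)
  cfg <- tiny_config()
  obj <- modinInit(cfg, seed = 3)
  m <- modin:::model_as_list(obj)
  maps <- modin:::modin_maps(cfg)
  B <- 3
  grids <- array(rnorm(B * 2 * 3 * 4), c(B, 2, 3, 4))
  fps <- matrix(rbinom(B * 16, 1, 0.4), B, 16)
  yt <- rnorm(B)
  lossfn <- function(params) {
    mm <- m; mm$params <- params
    fw <- modin:::modin_forward(mm, grids, fps, training = TRUE,
                                maps = maps)
    mean((fw$y - yt)^2)
  }
  fw <- modin:::modin_forward(m, grids, fps, training = TRUE, maps = maps)
  grad <- modin:::modin_backward(m, fw$cache, 2 * (fw$y - yt) / B)
  eps <- 1e-5
  groups <- list(c("conv1", "W"), c("conv2", "W"), c("bn1", "gamma"),
                 c("bn2", "beta"), c("fc", "W"), c("att", "Wk"),
                 c("att", "Wv"), c("att", "Wq"), c("att", "Wy"),
                 c("att", "by"))
  for (pth in groups) {
    arr <- m$params[[pth]]
    picks <- sample(length(arr), min(4, length(arr)))
    for (i in picks) {
      up <- m$params; up[[pth]][i] <- up[[pth]][i] + eps
      dn <- m$params; dn[[pth]][i] <- dn[[pth]][i] - eps
      num <- (lossfn(up) - lossfn(dn)) / (2 * eps)
      expect_equal(grad[[pth]][i], num, tolerance = 1e-4,
                   label = paste(paste(pth, collapse = "$"), i))
    }
  }
  for (l in 1:2) {
    arr <- m$params$mlp[[l]]$W
    for (i in sample(length(arr), 4)) {
      up <- m$params; up$mlp[[l]]$W[i] <- up$mlp[[l]]$W[i] + eps
      dn <- m$params; dn$mlp[[l]]$W[i] <- dn$mlp[[l]]$W[i] - eps
      num <- (lossfn(up) - lossfn(dn)) / (2 * eps)
      expect_equal(grad$mlp[[l]]$W[i], num, tolerance = 1e-4)
    }
  }
})

test_that("eval-mode cell encoding is deterministic and batch-independent", {
  set.seed(9)
  cfg <- tiny_config(channels = 3)
  model <- modinInit(cfg, seed = 4)
  grid <- array(rnorm(5 * 3 * 3 * 4), c(5, 3, 3, 4))
  gs <- new("CellGridSet", grid = grid,
            pad_mask = matrix(FALSE, 3, 4), channels = c("CNV", "MRNA", "METH"),
            sample_ids = paste0("c", 1:5),
            norms = matrix(1, 5, 3), p = 2)
  e1 <- encodeCells(model, gs)
  e2 <- encodeCells(model, gs)
  expect_identical(e1, e2)
  # two identical grids in one batch produce identical embeddings
  grid2 <- grid
  grid2[2, , , ] <- grid[1, , , ]
  gs2 <- gs; gs2@grid <- grid2
  e3 <- encodeCells(model, gs2)
  expect_equal(e3[1, ], e3[2, ], tolerance = 1e-12)
  # all-zero grid through a biasless network gives a zero embedding
  model0 <- model
  model0@params$fc$b <- numeric(cfg$d1)
  model0@params$bn1$beta <- numeric(2)
  model0@params$bn2$beta <- numeric(2)
  gs0 <- gs; gs0@grid <- array(0, dim(grid))
  expect_true(all(abs(encodeCells(model0, gs0)) < 1e-12))
})

test_that("appending extra zero-padded slots barely perturbs embeddings", {
  set.seed(31)
  cfg <- tiny_config(channels = 1, P = 3, G = 4)
  model <- modinInit(cfg, seed = 6)
  grid <- array(rnorm(2 * 1 * 3 * 4, sd = 0.1), c(2, 1, 3, 4))
  gs <- new("CellGridSet", grid = grid, pad_mask = matrix(FALSE, 3, 4),
            channels = "MRNA", sample_ids = c("a", "b"),
            norms = matrix(1, 2, 1), p = 2)
  e1 <- encodeCells(model, gs)
  # same data with two extra all-zero slot columns; wider fc input is
  # filled with zeros at the new positions, so reuse a model whose fc
  # weights are extended by zero rows at the appended columns
  cfg2 <- tiny_config(channels = 1, P = 3, G = 6)
  model2 <- modinInit(cfg2, seed = 6)
  model2@params$conv1 <- model@params$conv1
  model2@params$conv2 <- model@params$conv2
  model2@params$bn1 <- model@params$bn1
  model2@params$bn2 <- model@params$bn2
  # map pooled positions of the smaller grid into the larger flat layout
  W2 <- matrix(0, cfg2$flat_dim, cfg2$d1)
  P2 <- 2; G2small <- 2; G2big <- 3
  for (ch in 1:2) for (g2 in seq_len(G2small)) for (p2 in seq_len(P2)) {
    small_i <- (ch - 1) * (P2 * G2small) + (g2 - 1) * P2 + p2
    big_i <- (ch - 1) * (P2 * G2big) + (g2 - 1) * P2 + p2
    W2[big_i, ] <- model@params$fc$W[small_i, ]
  }
  model2@params$fc$W <- W2
  model2@params$fc$b <- model@params$fc$b
  grid2 <- array(0, c(2, 1, 3, 6))
  grid2[, , , 1:4] <- grid
  gs2 <- new("CellGridSet", grid = grid2,
             pad_mask = cbind(matrix(FALSE, 3, 4), matrix(TRUE, 3, 2)),
             channels = "MRNA", sample_ids = c("a", "b"),
             norms = matrix(1, 2, 1), p = 2)
  e2 <- encodeCells(model2, gs2)
  expect_lt(max(abs(e1 - e2)), 1e-4)
})
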