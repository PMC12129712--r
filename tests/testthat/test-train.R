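make_pairs <- function(n_cells = 10, n_drugs = 10, seed = 1) {
  set.seed(seed)
  df <- expand.grid(sample_id = paste0("c", seq_len(n_cells)),
                    drug_id = paste0("d", seq_len(n_drugs)),
                    stringsAsFactors = FALSE)
  df$ln_ic50 <- rnorm(nrow(df))
  df
}

test_that("the split is disjoint, exhaustive, drug-stratified and seeded", {
  pairs <- make_pairs()
  sp <- splitPairs(pairs, seed = 42, fraction = 0.2)
  expect_identical(nrow(sp$train), 80L)
  expect_identical(nrow(sp$test), 20L)
  key <- function(df) paste(df$sample_id, df$drug_id)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  expect_setequal(c(key(sp$train), key(sp$test)), key(pairs))
  # every drug appears in both partitions
  expect_setequal(unique(sp$train$drug_id), unique(pairs$drug_id))
  expect_setequal(unique(sp$test$drug_id), unique(pairs$drug_id))
  # reproducibility
  sp2 <- splitPairs(pairs, seed = 42, fraction = 0.2)
  expect_identical(sp, sp2)
  sp3 <- splitPairs(pairs, seed = 43, fraction = 0.2)
  expect_false(identical(key(sp$test), key(sp3$test)))
})

test_that("the cell-holdout split quarantines whole cells", {
  pairs <- make_pairs()
  sp <- splitCells(pairs, seed = 7, fraction = 0.2)
  held <- unique(sp$test$sample_id)
  expect_length(held, 2L)
  expect_length(intersect(held, unique(sp$train$sample_id)), 0L)
  # all pairs of a held-out cell are in test
  expect_identical(nrow(sp$test), 2L * 10L)
  expect_identical(nrow(sp$train) + nrow(sp$test), nrow(pairs))
  expect_identical(splitCells(pairs, seed = 7), sp)
})

test_that("a drug with a single pair goes to train with a warning", {
  pairs <- make_pairs(n_cells = 3, n_drugs = 3)
  pairs <- rbind(pairs, data.frame(sample_id = "c1", drug_id = "lonely",
                                   ln_ic50 = 0))
  expect_warning(sp <- splitPairs(pairs, seed = 1), "single pair")
  expect_true("lonely" %in% sp$train$drug_id)
  expect_false("lonely" %in% sp$test$drug_id)
})

test_that("metrics follow their defining formulas exactly", {
  m <- computeMetrics(c(1, 2, 3), c(1, 2, 3))
  expect_identical(c(m$mse, m$rmse), c(0, 0))
  expect_identical(m$r2, 1)

  m2 <- computeMetrics(c(0, 2), c(1, 1))
  expect_identical(c(m2$mse, m2$rmse, m2$r2), c(1, 1, 0))

  set.seed(11)
  y <- rnorm(50); yh <- rnorm(50)
  m3 <- computeMetrics(y, yh)
  expect_equal(m3$rmse^2, m3$mse, tolerance = 1e-9)
  expect_equal(m3$r2, 1 - m3$mse / mean((y - mean(y))^2), tolerance = 1e-12)
  expect_lte(m3$r2, 1)
  expect_equal(m3$pearson, cor(y, yh))

  expect_warning(m4 <- computeMetrics(c(2, 2, 2), c(1, 2, 3)),
                 "zero-variance")
  expect_true(is.nan(m4$r2))
})

tiny_training_world <- function(seed = 3) {
  set.seed(seed)
  n_cells <- 6; n_drugs <- 5
  cfg <- tiny_config(channels = 2, P = 3, G = 4, fp_bits = 16)
  grid <- array(rnorm(n_cells * 2 * 3 * 4), c(n_cells, 2, 3, 4))
  gs <- new("CellGridSet", grid = grid, pad_mask = matrix(FALSE, 3, 4),
            channels = c("CNV", "MRNA"),
            sample_ids = paste0("c", seq_len(n_cells)),
            norms = matrix(1, n_cells, 2), p = 2)
  fpm <- matrix(rbinom(n_drugs * 16, 1, 0.5), n_drugs, 16,
                dimnames = list(paste0("d", seq_len(n_drugs)), NULL))
  ds <- new("DrugSet", drug_ids = paste0("d", seq_len(n_drugs)),
            smiles = rep("C", n_drugs), fingerprints = fpm,
            dropped = data.frame())
  pairs <- expand.grid(sample_id = sampleIDs(gs), drug_id = drugIDs(ds),
                       stringsAsFactors = FALSE)
  pairs$ln_ic50 <- rnorm(nrow(pairs))
  list(cfg = cfg, gs = gs, ds = ds, pairs = pairs)
}

test_that("a zero learning rate leaves parameters untouched", {
  w <- tiny_training_world()
  fit <- trainModin(w$gs, w$ds, w$pairs, w$cfg, epochs = 3, batch_size = 8,
                    lr = 0, seed = 2)
  init <- modinInit(w$cfg, seed = 2)
  expect_equal(fit$model@params, init@params, tolerance = 1e-12)
})

test_that("training is deterministic under a fixed seed and reduces the loss", {
  w <- tiny_training_world()
  f1 <- trainModin(w$gs, w$ds, w$pairs, w$cfg, epochs = 8, batch_size = 8,
                   seed = 42)
  f2 <- trainModin(w$gs, w$ds, w$pairs, w$cfg, epochs = 8, batch_size = 8,
                   seed = 42)
  expect_equal(f1$model@params, f2$model@params, tolerance = 1e-12)
  m1 <- evaluateModel(f1$model, w$gs, w$ds, w$pairs)
  m2 <- evaluateModel(f2$model, w$gs, w$ds, w$pairs)
  expect_equal(m1$mse, m2$mse, tolerance = 1e-5)
  expect_lt(tail(f1$history$train_mse, 1), f1$history$train_mse[1])
})

test_that("seed summaries report mean and sample sd per metric", {
  reports <- data.frame(seed = 1:2, mse = c(0.8, 0.9), rmse = sqrt(c(0.8, 0.9)),
                        r2 = c(0.5, 0.6), pearson = c(0.7, 0.8))
  s <- summariseSeeds(reports)
  expect_equal(s$mean[s$metric == "mse"], 0.85)
  expect_equal(s$sd[s$metric == "mse"], sd(c(0.8, 0.9)))

  same <- data.frame(seed = 1:3, mse = rep(0.5, 3), rmse = rep(sqrt(0.5), 3),
                     r2 = rep(0.2, 3), pearson = rep(0.4, 3))
  s2 <- summariseSeeds(same)
  expect_true(all(s2$sd == 0))

  set.seed(4)
  five <- data.frame(seed = 1:5, mse = runif(5), rmse = runif(5),
                     r2 = runif(5), pearson = runif(5))
  s3 <- summariseSeeds(five)
  for (met in c("mse", "rmse", "r2", "pearson")) {
    expect_equal(s3$mean[s3$metric == met], mean(five[[met]]))
    expect_equal(s3$sd[s3$metric == met], sd(five[[met]]))
  }
  expect_match(s3$formatted[1], "^\\d\\.\\d{4} ± \\d\\.\\d{3}$")
})
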