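#' @include AllClasses.R nn-model.R nn-optim.R encode.R
NULL

#' Drug-stratified train/test split of response pairs
#'
#' Splits (cell, drug, LN_IC50) triples into disjoint, exhaustive train
#' and test partitions, stratified by drug so that every drug with enough
#' pairs appears in both.  A drug with a single pair goes to the training
#' set with a warning.  The split is reproducible given the seed.
#'
#' @param pairs data.frame with columns `sample_id`, `drug_id`,
#'   `ln_ic50`.
#' @param seed integer RNG seed.
#' @param fraction test-set share in (0, 1); default 0.2 (the 80/20
#'   protocol).
#' @return list with data.frames `train` and `test`.
#' @export
splitPairs <- function(pairs, seed, fraction = 0.2) {
  stopifnot(nrow(pairs) >= 5L, fraction > 0, fraction < 1,
            all(c("sample_id", "drug_id", "ln_ic50") %in% names(pairs)))
  set.seed(seed)
  test_idx <- integer(0)
  singletons <- 0L
  for (d in unique(pairs$drug_id)) {
    rows <- which(pairs$drug_id == d)
    if (length(rows) < 2L) { singletons <- singletons + 1L; next }
    ntest <- max(1L, round(length(rows) * fraction))
    if (ntest >= length(rows)) ntest <- length(rows) - 1L
    test_idx <- c(test_idx, sample(rows, ntest))
  }
  if (singletons > 0L)
    warning(singletons,
            " drug(s) with a single pair assigned entirely to train")
  test_idx <- sort(test_idx)
  list(train = pairs[setdiff(seq_len(nrow(pairs)), test_idx), ,
                     drop = FALSE],
       test = pairs[test_idx, , drop = FALSE])
}

#' Cell-holdout split of response pairs
#'
#' Holds out a fraction of the cells with all their pairs, so the test
#' set contains only cells never seen in training.  This measures
#' transfer to new samples — the regime in which the informativeness of
#' an omics channel is identifiable — whereas [splitPairs()] (the
#' standard protocol) shares every cell between train and test.
#'
#' @param pairs data.frame `sample_id, drug_id, ln_ic50`.
#' @param seed integer RNG seed.
#' @param fraction fraction of cells held out (default 0.2).
#' @return list with data.frames `train` and `test`.
#' @export
splitCells <- function(pairs, seed, fraction = 0.2) {
  stopifnot(fraction > 0, fraction < 1)
  cells <- unique(pairs$sample_id)
  stopifnot(length(cells) >= 2L)
  set.seed(seed)
  nhold <- max(1L, round(length(cells) * fraction))
  if (nhold >= length(cells)) nhold <- length(cells) - 1L
  hold <- sample(cells, nhold)
  sel <- pairs$sample_id %in% hold
  list(train = pairs[!sel, , drop = FALSE],
       test = pairs[sel, , drop = FALSE])
}

#' Regression metrics for LN_IC50 prediction
#'
#' MSE is the mean squared deviation, RMSE its square root, and R-squared
#' one minus the ratio of MSE to the variance of the truth (so RMSE^2 =
#' MSE holds identically and R^2 <= 1).  Pearson's r is reported
#' alongside.  A zero-variance truth vector has undefined R^2 and r,
#' reported as `NaN` with a warning.
#'
#' @param y numeric vector of true values.
#' @param yhat numeric vector of predictions.
#' @return named list: `mse`, `rmse`, `r2`, `pearson`, `n`.
#' @examples
#' computeMetrics(c(0, 2), c(1, 1))  # MSE 1, RMSE 1, R2 0
#' @export
computeMetrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1L)
  mse <- mean((y - yhat)^2)
  vy <- mean((y - mean(y))^2)
  if (vy == 0) {
    warning("zero-variance truth vector: R^2 and Pearson r undefined")
    r2 <- NaN
    pr <- NaN
  } else {
    r2 <- 1 - mse / vy
    pr <- if (stats::sd(yhat) == 0) NaN else stats::cor(y, yhat)
  }
  list(mse = mse, rmse = sqrt(mse), r2 = r2, pearson = pr, n = length(y))
}

#' Train the drug-cell interaction network
#'
#' Minimises MSE over (cell, drug, LN_IC50) triples with Adam.  Every
#' source of randomness (weight initialisation, epoch shuffling) is keyed
#' to `seed`, so two runs with the same seed and data are identical.
#' There is no early stopping; training runs the fixed number of epochs.
#'
#' @param grids a [CellGridSet-class] holding all referenced cells.
#' @param drugs a [DrugSet-class] holding all referenced drugs.
#' @param train_pairs data.frame `sample_id, drug_id, ln_ic50`.
#' @param config model configuration from [modinConfig()].
#' @param epochs training epochs (default 1000 as in the reference
#'   protocol; use far fewer at desk scale).
#' @param batch_size minibatch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed integer seed.
#' @param verbose print a loss line every `verbose` epochs (0 = silent).
#' @return list: `model` (trained [ModinModel-class]) and `history`
#'   (data.frame `epoch, train_mse`).
#' @export
trainModin <- function(grids, drugs, train_pairs, config, epochs = 1000L,
                       batch_size = 32L, lr = 1e-3, seed = 42L,
                       verbose = 0L) {
  object <- modinInit(config, seed = seed)
  m <- model_as_list(object)
  maps <- modin_maps(config)
  ci <- match(train_pairs$sample_id, grids@sample_ids)
  di <- match(train_pairs$drug_id, drugs@drug_ids)
  if (anyNA(ci) || anyNA(di))
    stop("train pairs reference unknown cell or drug IDs")
  yall <- train_pairs$ln_ic50
  stopifnot(all(is.finite(yall)))
  n <- nrow(train_pairs)
  state <- adam_init(m$params)
  history <- numeric(epochs)
  set.seed(seed + 1L)
  fpm <- drugs@fingerprints
  pad_s <- which(as.vector(grids@pad_mask))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (s in seq(1L, n, by = batch_size)) {
      sel <- ord[s:min(s + batch_size - 1L, n)]
      B <- length(sel)
      gb <- grids@grid[ci[sel], , , , drop = FALSE]
      fb <- fpm[di[sel], , drop = FALSE]
      fw <- modin_forward(m, gb, fb, training = TRUE, maps = maps,
                          pad_s = pad_s)
      m$buffers <- fw$buffers
      err <- fw$y - yall[sel]
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      tot <- tot + loss * B
      grads <- modin_backward(m, fw$cache, 2 * err / B)
      st <- adam_step(m$params, grads, state, lr = lr)
      m$params <- st$params
      state <- st$state
    }
    history[ep] <- tot / n
    if (verbose > 0L && ep %% verbose == 0L)
      message(sprintf("epoch %d  train MSE %.4f", ep, history[ep]))
  }
  object@params <- m$params
  object@buffers <- m$buffers
  object@trained <- TRUE
  list(model = object,
       history = data.frame(epoch = seq_len(epochs), train_mse = history))
}

#' Evaluate a trained model on held-out pairs
#'
#' @param model a trained [ModinModel-class].
#' @param grids a [CellGridSet-class].
#' @param drugs a [DrugSet-class].
#' @param test_pairs data.frame `sample_id, drug_id, ln_ic50`.
#' @return metrics list as from [computeMetrics()], plus `predictions`
#'   (data.frame).
#' @export
evaluateModel <- function(model, grids, drugs, test_pairs) {
  stopifnot(nrow(test_pairs) >= 1L)
  pred <- predictPairs(model, grids, drugs, test_pairs)
  met <- computeMetrics(test_pairs$ln_ic50, pred$ln_ic50_pred)
  met$predictions <- cbind(pred, ln_ic50 = test_pairs$ln_ic50)
  met
}

#' Train/evaluate across several seeds and summarise
#'
#' Runs the full split/train/evaluate protocol once per seed and reports
#' per-seed metrics plus their mean and sample standard deviation,
#' formatted "mean +/- sd".
#'
#' @param grids,drugs,pairs data as for [trainModin()].
#' @param config model configuration.
#' @param seeds integer vector of seeds (the reference protocol uses 42,
#'   1234, 2023, 3407, 619).
#' @param fraction test share (default 0.2).
#' @param ... passed to [trainModin()] (`epochs`, `batch_size`, `lr`).
#' @return list: `per_seed` (data.frame), `summary` (data.frame with
#'   mean, sd and a formatted column per metric).
#' @export
multiSeedRun <- function(grids, drugs, pairs, config,
                         seeds = c(42L, 1234L, 2023L, 3407L, 619L),
                         fraction = 0.2, ...) {
  stopifnot(length(seeds) >= 1L)
  rows <- lapply(seeds, function(sd) {
    sp <- splitPairs(pairs, seed = sd, fraction = fraction)
    fit <- trainModin(grids, drugs, sp$train, config, seed = sd, ...)
    met <- evaluateModel(fit$model, grids, drugs, sp$test)
    data.frame(seed = sd, mse = met$mse, rmse = met$rmse, r2 = met$r2,
               pearson = met$pearson)
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed, summary = summariseSeeds(per_seed))
}

#' Summarise per-seed metric reports
#'
#' @param per_seed data.frame with one row per seed and numeric metric
#'   columns (`mse`, `rmse`, `r2`, `pearson`).
#' @return data.frame with `metric`, `mean`, `sd` and `formatted`
#'   ("0.8254 +/- 0.013" style).
#' @export
summariseSeeds <- function(per_seed) {
  metrics <- setdiff(names(per_seed), "seed")
  do.call(rbind, lapply(metrics, function(mname) {
    x <- per_seed[[mname]]
    mu <- mean(x)
    sdv <- if (length(x) > 1L) stats::sd(x) else 0
    data.frame(metric = mname, mean = mu, sd = sdv,
               formatted = sprintf("%.4f ± %.3f", mu, sdv),
               stringsAsFactors = FALSE)
  }))
}

#' Omics-combination ablation harness
#'
#' Re-runs split/train/evaluate for each requested subset of omics
#' channels.  Missing channels are dropped from the feature grid (the
#' model input has fewer channels), not zero-filled.
#'
#' @param omics named list of imputed [OmicsMatrix-class] objects sharing
#'   gene ordering (names are modalities).
#' @param pmap a [PathwayGeneMap-class].
#' @param drugs a [DrugSet-class].
#' @param pairs response data.frame.
#' @param config_fn function(channels) returning a [modinConfig()] for a
#'   given channel count (the grid geometry is fixed by `pmap`).
#' @param subsets list of character vectors of modality names; default
#'   all 7 non-empty combinations.
#' @param seed split/train seed (default 42).
#' @param p grid norm order.
#' @param holdout `"pair"` (default, the standard drug-stratified
#'   pair-level split) or `"cell"` to evaluate on held-out cells.  Note
#'   that under pair-level splits every cell is seen in training, so the
#'   network can identify a cell from any channel's unique pattern and
#'   memorise its response profile — channel subsets then score within
#'   noise of each other; see the package vignette.
#' @param ... passed to [trainModin()].
#' @return data.frame with one row per subset: `subset, channels, mse,
#'   rmse, r2, pearson`.
#' @export
runAblation <- function(omics, pmap, drugs, pairs, config_fn,
                        subsets = NULL, seed = 42L, p = 2,
                        holdout = c("pair", "cell"), ...) {
  holdout <- match.arg(holdout)
  mods <- names(omics)
  stopifnot(length(mods) >= 1L, !is.null(mods))
  if (is.null(subsets)) {
    subsets <- unlist(lapply(seq_along(mods), function(k)
      utils::combn(mods, k, simplify = FALSE)), recursive = FALSE)
  }
  sp <- if (holdout == "cell") splitCells(pairs, seed = seed)
        else splitPairs(pairs, seed = seed)
  rows <- lapply(subsets, function(sub) {
    grids <- assembleGrid(omics[sub], pmap, p = p)
    cfg <- config_fn(length(sub))
    fit <- trainModin(grids, drugs, sp$train, cfg, seed = seed, ...)
    met <- evaluateModel(fit$model, grids, drugs, sp$test)
    data.frame(subset = paste(sub, collapse = "+"),
               channels = length(sub), mse = met$mse, rmse = met$rmse,
               r2 = met$r2, pearson = met$pearson,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
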