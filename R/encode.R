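#' @include AllClasses.R nn-model.R
NULL

#' Encode cell feature grids into fixed-length embeddings
#'
#' Runs the stacked-CNN cell-line extractor in eval mode (batch-norm uses
#' running statistics), so outputs are deterministic and independent of
#' batch composition.
#'
#' @param model a [ModinModel-class].
#' @param grids a [CellGridSet-class] whose channel count matches the
#'   model configuration.
#' @return numeric matrix (cells x d1) with sample IDs as row names.
#' @export
encodeCells <- function(model, grids) {
  stopifnot(is(model, "ModinModel"), is(grids, "CellGridSet"))
  cfg <- model@config
  d <- dim(grids@grid)
  if (d[2] != cfg$channels || d[3] != cfg$P || d[4] != cfg$G)
    stop("grid shape (", paste(d[2:4], collapse = "x"),
         ") does not match model config (",
         paste(c(cfg$channels, cfg$P, cfg$G), collapse = "x"), ")")
  m <- model_as_list(model)
  maps <- modin_maps(cfg)
  # cell path only: reuse the full forward with dummy fingerprints
  fps <- matrix(0, d[1], cfg$fp_bits)
  out <- modin_forward(m, grids@grid, fps, training = FALSE, maps = maps,
                       pad_s = which(as.vector(grids@pad_mask)))
  H <- out$Hc
  rownames(H) <- grids@sample_ids
  H
}

#' Encode drug fingerprints into dense embeddings
#'
#' Applies the MLP drug extractor.  Pure per-row computation: the
#' embedding of a drug does not depend on which other drugs share the
#' batch.
#'
#' @param model a [ModinModel-class].
#' @param drugs a [DrugSet-class] (fingerprint width must match the model
#'   configuration).
#' @return numeric matrix (drugs x d2) with drug IDs as row names.
#' @export
encodeDrugs <- function(model, drugs) {
  stopifnot(is(model, "ModinModel"), is(drugs, "DrugSet"))
  cfg <- model@config
  fps <- drugs@fingerprints
  if (ncol(fps) != cfg$fp_bits)
    stop("fingerprint width ", ncol(fps), " does not match config fp_bits ",
         cfg$fp_bits)
  p <- model@params
  X <- fps
  for (l in seq_along(p$mlp)) {
    X <- linear_forward(X, p$mlp[[l]]$W, p$mlp[[l]]$b)$out
    if (l < length(p$mlp)) X <- relu_forward(X)$out
  }
  rownames(X) <- drugs@drug_ids
  X
}

#' Predict LN_IC50 for (cell, drug) pairs
#'
#' Vectorised, order-preserving application of the cross-modal attention
#' head in eval mode.
#'
#' @param model a trained [ModinModel-class].
#' @param grids a [CellGridSet-class].
#' @param drugs a [DrugSet-class].
#' @param pairs data.frame with columns `sample_id` and `drug_id`.
#' @param batch_size forward batch size (default 256).
#' @return data.frame `sample_id, drug_id, ln_ic50_pred` in input order.
#' @export
predictPairs <- function(model, grids, drugs, pairs, batch_size = 256L) {
  stopifnot(is(model, "ModinModel"),
            all(c("sample_id", "drug_id") %in% names(pairs)))
  ci <- match(pairs$sample_id, grids@sample_ids)
  di <- match(pairs$drug_id, drugs@drug_ids)
  if (anyNA(ci))
    stop("unknown sample_id(s): ",
         paste(unique(pairs$sample_id[is.na(ci)]), collapse = ", "))
  if (anyNA(di))
    stop("unknown drug_id(s): ",
         paste(unique(pairs$drug_id[is.na(di)]), collapse = ", "))
  n <- nrow(pairs)
  if (n == 0L)
    return(data.frame(sample_id = character(0), drug_id = character(0),
                      ln_ic50_pred = numeric(0)))
  m <- model_as_list(model)
  maps <- modin_maps(model@config)
  pad_s <- which(as.vector(grids@pad_mask))
  preds <- numeric(n)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    sel <- s:min(s + batch_size - 1L, n)
    gb <- grids@grid[ci[sel], , , , drop = FALSE]
    fb <- drugs@fingerprints[di[sel], , drop = FALSE]
    preds[sel] <- modin_forward(m, gb, fb, training = FALSE, maps = maps,
                                pad_s = pad_s)$y
  }
  data.frame(sample_id = pairs$sample_id, drug_id = pairs$drug_id,
             ln_ic50_pred = preds, stringsAsFactors = FALSE)
}
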