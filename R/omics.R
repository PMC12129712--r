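#' @include AllClasses.R
NULL

#' Read a sample-by-gene omics matrix from delimited text
#'
#' Expects a header row of gene symbols and a first column of sample IDs.
#' The delimiter is auto-detected (tab or comma) unless given.  The token
#' used for missing values is converted to `NA`.
#'
#' @param path file path.
#' @param modality `"CNV"`, `"MRNA"` or `"METH"`.
#' @param sep field delimiter; `NULL` (default) auto-detects.
#' @param missing_token string treated as missing in addition to `NA`
#'   (default `"NA"`).
#' @return an [OmicsMatrix-class].
#' @export
readOmicsMatrix <- function(path, modality, sep = NULL, missing_token = "NA") {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          na.strings = c("NA", missing_token),
                          check.names = FALSE, stringsAsFactors = FALSE)
  OmicsMatrix(as.matrix(df), modality)
}

#' Read pathway gene sets from a GMT file
#'
#' Thin wrapper over `fgsea::gmtPathways()` returning a
#' [PathwayGeneMap-class].
#'
#' @param path GMT file path.
#' @return a [PathwayGeneMap-class].
#' @export
readPathwayGMT <- function(path) {
  PathwayGeneMap(fgsea::gmtPathways(path))
}

#' Write pathway gene sets to a GMT file
#'
#' @param pmap a [PathwayGeneMap-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePathwayGMT <- function(pmap, path) {
  lines <- vapply(pmap@pathway_ids, function(p) {
    paste(c(p, "na", pmap@members[[p]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict pathways to an available gene universe
#'
#' Drops member genes absent from `genes` (with a message) and removes
#' pathways left empty.
#'
#' @param pmap a [PathwayGeneMap-class].
#' @param genes character vector of available gene IDs.
#' @return a filtered [PathwayGeneMap-class].
#' @export
restrictPathways <- function(pmap, genes) {
  mem <- lapply(pmap@members, function(g) g[g %in% genes])
  lost <- sum(lengths(pmap@members)) - sum(lengths(mem))
  if (lost > 0)
    message(lost, " pathway member gene(s) absent from the shared gene set; dropped")
  keep <- lengths(mem) > 0L
  if (!all(keep))
    warning(sum(!keep), " pathway(s) left empty after restriction; removed")
  PathwayGeneMap(mem[keep])
}

#' Restrict omics matrices to their shared gene set
#'
#' Genes lacking concurrent measurement across all supplied modalities are
#' excluded; the returned matrices share one gene ordering (the sorted
#' intersection).  Sample sets must be identical across modalities.
#'
#' @param matrices list of [OmicsMatrix-class] objects (usually CNV, MRNA,
#'   METH).
#' @return list with elements `genes` (sorted shared gene IDs) and
#'   `matrices` (the column-subset [OmicsMatrix-class] list, same order
#'   as the input).
#' @examples
#' m <- function(g) matrix(0, 1, length(g), dimnames = list("s1", g))
#' om <- list(OmicsMatrix(m(c("A", "B", "C")), "CNV"),
#'            OmicsMatrix(m(c("B", "C", "D")), "MRNA"),
#'            OmicsMatrix(m(c("B", "C")), "METH"))
#' intersectGenes(om)$genes
#' @export
intersectGenes <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  for (m in matrices) stopifnot(is(m, "OmicsMatrix"))
  samp <- lapply(matrices, sampleIDs)
  ref <- samp[[1]]
  for (i in seq_along(samp)[-1]) {
    if (!identical(sort(samp[[i]]), sort(ref))) {
      diff <- c(setdiff(ref, samp[[i]]), setdiff(samp[[i]], ref))
      stop("sample sets differ between modalities ",
           modality(matrices[[1]]), " and ", modality(matrices[[i]]),
           "; offending samples: ", paste(diff, collapse = ", "))
    }
  }
  shared <- Reduce(intersect, lapply(matrices, geneIDs))
  if (length(shared) == 0L)
    stop("no genes are measured across all modalities: ",
         paste(vapply(matrices, modality, ""), collapse = ", "))
  shared <- sort(shared)
  out <- lapply(matrices, function(m) {
    OmicsMatrix(omicsValues(m)[ref, shared, drop = FALSE], modality(m))
  })
  names(out) <- vapply(matrices, modality, "")
  list(genes = shared, matrices = out)
}

#' Mean-impute missing entries of an omics matrix
#'
#' Every missing (`NA`) entry of a gene column is replaced by the mean of
#' that gene's present entries, so that the downstream feature grid is
#' dense.  Genes whose missingness exceeds `flag_threshold` (the fraction
#' triggering pathway-level quality flags) are reported via a message;
#' genes with no present entry at all are filled with `fill_empty` and a
#' warning is emitted.  Present values are never altered.
#'
#' @param x an [OmicsMatrix-class] or plain numeric matrix
#'   (samples x genes).
#' @param flag_threshold fraction of missingness above which a gene is
#'   reported (default 0.5).
#' @param fill_empty value used for all-missing genes (default 0).
#' @return object of the same class as `x`, dense.
#' @export
imputeMissing <- function(x, flag_threshold = 0.5, fill_empty = 0) {
  v <- if (is(x, "OmicsMatrix")) omicsValues(x) else x
  nmiss <- colSums(is.na(v))
  if (any(nmiss > 0)) {
    frac <- nmiss / nrow(v)
    heavy <- which(frac > flag_threshold & frac < 1)
    if (length(heavy))
      message(length(heavy), " gene(s) exceed ",
              round(100 * flag_threshold), "% missingness; mean-imputed")
    empty <- which(nmiss == nrow(v))
    for (j in which(nmiss > 0L)) {
      miss <- is.na(v[, j])
      v[miss, j] <- if (all(miss)) fill_empty else mean(v[!miss, j])
    }
    if (length(empty))
      warning(length(empty), " gene(s) entirely missing; filled with ",
              fill_empty)
  }
  if (is(x, "OmicsMatrix")) OmicsMatrix(v, modality(x)) else v
}

#' Normalise a vector to unit p-norm
#'
#' Divides `x` by its p-norm so the result has `‖x‖_p = 1`.  A zero
#' vector is returned unchanged with a warning (its norm is zero).
#'
#' @param x finite numeric vector.
#' @param p norm order, 1 or 2 (default 2).
#' @return numeric vector with unit p-norm (or zeros).
#' @examples
#' pnormNormalize(c(3, 4))          # (0.6, 0.8)
#' pnormNormalize(rep(1, 4), p = 1) # all 0.25
#' @export
pnormNormalize <- function(x, p = 2) {
  stopifnot(all(is.finite(x)), p %in% c(1, 2))
  nrm <- if (p == 1) sum(abs(x)) else sqrt(sum(x^2))
  if (nrm == 0) {
    warning("zero vector has no p-norm direction; returned unchanged")
    return(x)
  }
  x / nrm
}

#' Assemble per-cell pathway-by-gene feature grids
#'
#' Builds the cell-side model input: one `channels x pathways x slots`
#' grid per sample.  For each sample and channel, the vector of
#' pathway-indexed values (members of every pathway, in order, genes
#' shared by several pathways appearing once per pathway) is normalised
#' to unit p-norm and placed at `(pathway, slot)` positions.  Slots
#' beyond a pathway's size are zero padding, recorded in the pad mask,
#' so the non-pad entries of every sample/channel plane have p-norm 1.
#' The per-sample/channel norms are stored so raw values remain
#' recoverable.
#'
#' @param matrices named list of imputed [OmicsMatrix-class] objects
#'   sharing sample order and gene ordering (see [intersectGenes()],
#'   [imputeMissing()]).
#' @param pmap a [PathwayGeneMap-class]; every member gene must be present
#'   in the matrices.
#' @param p norm order (1 or 2, default 2).
#' @return a [CellGridSet-class].
#' @export
assembleGrid <- function(matrices, pmap, p = 2) {
  stopifnot(length(matrices) >= 1L)
  genes <- geneIDs(matrices[[1]])
  samples <- sampleIDs(matrices[[1]])
  for (m in matrices) {
    stopifnot(identical(geneIDs(m), genes),
              identical(sampleIDs(m), samples))
    if (anyNA(omicsValues(m)))
      stop("matrix ", modality(m), " contains NA; impute first")
  }
  for (q in pmap@pathway_ids) {
    absent <- setdiff(pmap@members[[q]], genes)
    if (length(absent))
      stop("pathway ", q, " references gene(s) absent from the shared set: ",
           paste(absent, collapse = ", "))
  }
  P <- length(pmap@pathway_ids)
  G <- padWidth(pmap)
  C <- length(matrices)
  B <- length(samples)
  pad_mask <- matrix(TRUE, P, G,
                     dimnames = list(pmap@pathway_ids, NULL))
  idx <- matrix(NA_integer_, P, G)
  for (qi in seq_len(P)) {
    mem <- pmap@members[[qi]]
    idx[qi, seq_along(mem)] <- match(mem, genes)
    pad_mask[qi, seq_along(mem)] <- FALSE
  }
  grid <- array(0, dim = c(B, C, P, G))
  norms <- matrix(0, B, C, dimnames = list(samples, names(matrices)))
  placed <- idx[!pad_mask]   # gene column per non-pad slot
  for (ci in seq_len(C)) {
    v <- omicsValues(matrices[[ci]])
    for (b in seq_len(B)) {
      x <- v[b, placed]
      nrm <- if (p == 1) sum(abs(x)) else sqrt(sum(x^2))
      norms[b, ci] <- nrm
      xn <- if (nrm == 0) x else x / nrm
      plane <- matrix(0, P, G)
      plane[!pad_mask] <- xn
      grid[b, ci, , ] <- plane
    }
  }
  ch <- names(matrices)
  if (is.null(ch)) ch <- vapply(matrices, modality, "")
  new("CellGridSet", grid = grid, pad_mask = pad_mask, channels = ch,
      sample_ids = samples, norms = norms, p = p)
}
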