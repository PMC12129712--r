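#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "OmicsMatrix", function(x) rownames(x@values))

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "CellGridSet", function(x) x@sample_ids)

#' @rdname geneIDs
#' @export
setMethod("geneIDs", "OmicsMatrix", function(x) colnames(x@values))

#' @rdname modality
#' @export
setMethod("modality", "OmicsMatrix", function(x) x@modality)

#' @rdname omicsValues
#' @export
setMethod("omicsValues", "OmicsMatrix", function(x) x@values)

#' @rdname pathwayIDs
#' @export
setMethod("pathwayIDs", "PathwayGeneMap", function(x) x@pathway_ids)

#' @rdname pathwayMembers
#' @export
setMethod("pathwayMembers", "PathwayGeneMap", function(x) x@members)

#' @rdname drugIDs
#' @export
setMethod("drugIDs", "DrugSet", function(x) x@drug_ids)

#' Fingerprint matrix of a DrugSet
#' @param x a [DrugSet-class].
#' @return 0/1 integer matrix (drugs x bits).
#' @export
fingerprints <- function(x) {
  stopifnot(is(x, "DrugSet"))
  x@fingerprints
}

#' Subset a DrugSet
#' @param x a [DrugSet-class].
#' @param i index vector (positions, logicals or drug IDs).
#' @param j,...,drop ignored (matrix-style signature).
#' @return a [DrugSet-class] with the selected drugs.
#' @export
setMethod("[", "DrugSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@drug_ids)
  new("DrugSet", drug_ids = x@drug_ids[i], smiles = x@smiles[i],
      fingerprints = x@fingerprints[i, , drop = FALSE],
      dropped = x@dropped)
})

#' @rdname consensusMatrix
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(x, k) {
  if (missing(k)) k <- x@chosen_k
  m <- x@consensus[[as.character(k)]]
  if (is.null(m)) stop("no consensus matrix for k = ", k)
  m
})

#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "ConsensusResult", function(x, k) {
  if (missing(k)) k <- x@chosen_k
  l <- x@labels[[as.character(k)]]
  if (is.null(l)) stop("no labels for k = ", k)
  l
})

#' @rdname chosenK
#' @export
setMethod("chosenK", "ConsensusResult", function(x) x@chosen_k)

setMethod("show", "OmicsMatrix", function(object) {
  v <- object@values
  cat(sprintf("OmicsMatrix [%s]: %d samples x %d genes (%.2f%% missing)\n",
              object@modality, nrow(v), ncol(v),
              100 * mean(is.na(v))))
})

setMethod("show", "PathwayGeneMap", function(object) {
  n <- lengths(object@members)
  cat(sprintf("PathwayGeneMap: %d pathways, sizes %d..%d (grid width %d)\n",
              length(n), min(n), max(n), max(n)))
})

setMethod("show", "CellGridSet", function(object) {
  d <- dim(object@grid)
  cat(sprintf(
    "CellGridSet: %d cells, %d channel(s) [%s], %d pathways x %d slots (L%g-normalised)\n",
    d[1], d[2], paste(object@channels, collapse = ","), d[3], d[4], object@p))
})

setMethod("show", "DrugSet", function(object) {
  cat(sprintf("DrugSet: %d drugs, %d-bit fingerprints (%d record(s) dropped)\n",
              length(object@drug_ids), ncol(object@fingerprints),
              nrow(object@dropped)))
})

setMethod("show", "ModinModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf(
    "ModinModel: %d channel(s), %dx%d grid, kernel %d, d1=%d, d2=%d, latent=%d, heads=%d, tokens=%d\n",
    cfg$channels, cfg$P, cfg$G, cfg$kernel_size, cfg$d1, cfg$d2,
    cfg$latent_dim, cfg$heads, cfg$tokens_per_modality))
  cat(sprintf("  %d parameters; trained: %s\n", np, object@trained))
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: k in {%s}; chosen k = %d\n",
              paste(object@k_values, collapse = ","), object@chosen_k))
  cat("  delta-area:",
      paste(sprintf("%s=%.3f", object@k_values,
                    object@delta_area), collapse = " "), "\n")
})
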