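#' @import methods
NULL

MODALITIES <- c("CNV", "MRNA", "METH")

#' OmicsMatrix: one modality's sample-by-gene value matrix
#'
#' Container for a single omics modality.  Values are on the source
#' platform's scale: log2 ratios for copy number (CNV), RMA log-intensity
#' for mRNA expression (MRNA), beta values for DNA methylation (METH).
#' Missing measurements are encoded as `NA`; infinities are rejected.
#'
#' @slot modality character, one of `"CNV"`, `"MRNA"`, `"METH"`.
#' @slot values numeric matrix, samples in rows, genes in columns, with
#'   both dimnames set.
#'
#' @seealso [OmicsMatrix()], [intersectGenes()], [assembleGrid()]
#' @export
setClass("OmicsMatrix",
         representation(modality = "character", values = "matrix"))

setValidity("OmicsMatrix", function(object) {
  msg <- character(0)
  if (length(object@modality) != 1L || !object@modality %in% MODALITIES)
    msg <- c(msg, sprintf("modality must be one of %s",
                          paste(MODALITIES, collapse = ", ")))
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have sample (row) and gene (column) names")
  if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
    msg <- c(msg, "gene_ids must be unique")
  if (any(is.infinite(v)))
    msg <- c(msg, "values contain infinities")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix (samples x genes) with dimnames.
#' @param modality `"CNV"`, `"MRNA"` or `"METH"`.
#' @return an [OmicsMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
#' OmicsMatrix(m, "CNV")
#' @export
OmicsMatrix <- function(values, modality) {
  new("OmicsMatrix", modality = toupper(modality), values = values)
}

#' PathwayGeneMap: ordered pathway -> gene-member index
#'
#' Holds the pathway gene sets used to lay genes out on the feature grid.
#' Member order within a pathway is preserved; a gene belonging to several
#' pathways appears in each of them (no deduplication across pathways).
#'
#' @slot pathway_ids character vector of pathway identifiers.
#' @slot members named list of character vectors (gene IDs per pathway).
#' @export
setClass("PathwayGeneMap",
         representation(pathway_ids = "character", members = "list"))

setValidity("PathwayGeneMap", function(object) {
  msg <- character(0)
  if (length(object@pathway_ids) < 1L)
    msg <- c(msg, "need at least one pathway")
  if (length(object@members) != length(object@pathway_ids))
    msg <- c(msg, "members and pathway_ids lengths differ")
  if (any(lengths(object@members) == 0L))
    msg <- c(msg, "pathway member lists must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a PathwayGeneMap
#'
#' @param members named list of gene-ID character vectors.
#' @return a [PathwayGeneMap-class].
#' @export
PathwayGeneMap <- function(members) {
  ids <- names(members)
  if (is.null(ids)) ids <- paste0("pathway", seq_along(members))
  new("PathwayGeneMap", pathway_ids = ids,
      members = stats::setNames(as.list(members), ids))
}

#' Largest pathway size (gene-slot width of the feature grid)
#' @param pmap a [PathwayGeneMap-class].
#' @return integer G, the padded gene-slot count.
#' @export
padWidth <- function(pmap) max(lengths(pmap@members))

#' CellGridSet: per-cell 3-channel pathway-by-gene feature grids
#'
#' The cell-side model input.  `grid[b, c, q, j]` holds channel `c`'s
#' normalised value for sample `b`, pathway `q`, gene slot `j`.  Slots
#' beyond a pathway's gene count are padding and are exactly zero;
#' `pad_mask[q, j]` is `TRUE` for those slots.  `norms[b, c]` stores the
#' p-norm each sample/channel vector was divided by, so raw values are
#' recoverable.
#'
#' @slot grid 4-d numeric array `(samples, channels, pathways, slots)`.
#' @slot pad_mask logical matrix `(pathways, slots)`.
#' @slot channels character vector of modality names.
#' @slot sample_ids character vector.
#' @slot norms numeric matrix `(samples, channels)`.
#' @slot p numeric norm order used (1 or 2).
#' @export
setClass("CellGridSet",
         representation(grid = "array", pad_mask = "matrix",
                        channels = "character", sample_ids = "character",
                        norms = "matrix", p = "numeric"))

setValidity("CellGridSet", function(object) {
  d <- dim(object@grid)
  msg <- character(0)
  if (length(d) != 4L) msg <- c(msg, "grid must be a 4-d array")
  else {
    if (d[1] != length(object@sample_ids))
      msg <- c(msg, "grid sample dimension mismatch")
    if (d[2] != length(object@channels))
      msg <- c(msg, "grid channel dimension mismatch")
    if (!all(d[3:4] == dim(object@pad_mask)))
      msg <- c(msg, "pad_mask shape mismatch")
    pad <- which(object@pad_mask)
    if (length(pad)) {
      # rows of g2 index (pathway, slot) positions, columns samples/channels
      g2 <- matrix(aperm(object@grid, c(3, 4, 1, 2)), d[3] * d[4])
      if (any(g2[pad, ] != 0)) msg <- c(msg, "padded slots must be zero")
    }
  }
  if (length(msg)) msg else TRUE
})

#' DrugSet: drug IDs, SMILES and hashed circular fingerprints
#'
#' @slot drug_ids character vector.
#' @slot smiles character vector, parallel to `drug_ids`.
#' @slot fingerprints 0/1 integer matrix `(drugs, bits)`, 2048 bits by
#'   default.
#' @slot dropped data.frame of rejected records (`drug_id`, `smiles`,
#'   `reason`), typically unparseable SMILES.
#' @export
setClass("DrugSet",
         representation(drug_ids = "character", smiles = "character",
                        fingerprints = "matrix", dropped = "data.frame"))

setValidity("DrugSet", function(object) {
  msg <- character(0)
  n <- length(object@drug_ids)
  if (length(object@smiles) != n) msg <- c(msg, "smiles length mismatch")
  if (nrow(object@fingerprints) != n)
    msg <- c(msg, "fingerprint row count mismatch")
  fp <- object@fingerprints
  if (length(fp) && !all(fp %in% c(0L, 1L)))
    msg <- c(msg, "fingerprints must be 0/1")
  if (anyDuplicated(object@drug_ids)) msg <- c(msg, "drug_ids must be unique")
  if (length(msg)) msg else TRUE
})

#' ModinModel: architecture configuration plus learned parameters
#'
#' Bundles the resolved model configuration (see [modinConfig()]), the
#' trainable parameter list, non-trainable buffers (batch-norm running
#' statistics), and a trained flag.
#'
#' @slot config named list.
#' @slot params named list of numeric arrays.
#' @slot buffers named list (batch-norm running mean/var).
#' @slot trained logical.
#' @export
setClass("ModinModel",
         representation(config = "list", params = "list", buffers = "list",
                        trained = "logical"))

#' ConsensusResult: consensus clustering output
#'
#' @slot k_values integer vector of evaluated cluster numbers.
#' @slot consensus named list of consensus matrices, one per k.
#' @slot cdf named list of empirical CDF vectors (100 bins) per k.
#' @slot area numeric, area under the consensus CDF per k.
#' @slot delta_area numeric, relative change in CDF area per k.
#' @slot chosen_k integer.
#' @slot labels named list of integer label vectors, one per k.
#' @export
setClass("ConsensusResult",
         representation(k_values = "integer", consensus = "list",
                        cdf = "list", area = "numeric",
                        delta_area = "numeric", chosen_k = "integer",
                        labels = "list"))

setValidity("ConsensusResult", function(object) {
  msg <- character(0)
  for (k in as.character(object@k_values)) {
    m <- object@consensus[[k]]
    if (is.null(m)) { msg <- c(msg, paste("missing consensus for k =", k)); next }
    if (max(abs(m - t(m))) > 1e-12) msg <- c(msg, "consensus not symmetric")
    if (any(abs(diag(m) - 1) > 1e-12)) msg <- c(msg, "diagonal must be 1")
    if (any(m < 0 | m > 1)) msg <- c(msg, "consensus entries outside [0,1]")
  }
  if (length(msg)) unique(msg) else TRUE
})
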