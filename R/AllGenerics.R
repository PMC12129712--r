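#' @include AllClasses.R
NULL

#' Sample identifiers of an object
#'
#' @param x an object carrying samples (an [OmicsMatrix-class],
#'   [CellGridSet-class], ...).
#' @return character vector of sample IDs.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Gene identifiers of an object
#' @param x an object carrying genes.
#' @return character vector of gene IDs.
#' @export
setGeneric("geneIDs", function(x) standardGeneric("geneIDs"))

#' Drug identifiers of an object
#' @param x an object carrying drugs.
#' @return character vector of drug IDs.
#' @export
setGeneric("drugIDs", function(x) standardGeneric("drugIDs"))

#' Omics modality of a matrix
#' @param x an [OmicsMatrix-class].
#' @return one of `"CNV"`, `"MRNA"`, `"METH"`.
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' Value matrix of an omics object
#' @param x an [OmicsMatrix-class].
#' @return numeric matrix, samples in rows, genes in columns.
#' @export
setGeneric("omicsValues", function(x) standardGeneric("omicsValues"))

#' Pathway identifiers
#' @param x a [PathwayGeneMap-class].
#' @return character vector of pathway IDs.
#' @export
setGeneric("pathwayIDs", function(x) standardGeneric("pathwayIDs"))

#' Per-pathway member gene lists
#' @param x a [PathwayGeneMap-class].
#' @return named list of character vectors.
#' @export
setGeneric("pathwayMembers", function(x) standardGeneric("pathwayMembers"))

#' Consensus matrix for a given cluster number
#' @param x a [ConsensusResult-class].
#' @param k cluster number; defaults to the chosen k.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
setGeneric("consensusMatrix", function(x, k) standardGeneric("consensusMatrix"))

#' Cluster labels of a consensus clustering
#' @param x a [ConsensusResult-class].
#' @param k cluster number; defaults to the chosen k.
#' @return integer vector of labels in `1..k`, named by sample.
#' @export
setGeneric("clusterLabels", function(x, k) standardGeneric("clusterLabels"))

#' Chosen number of clusters
#' @param x a [ConsensusResult-class].
#' @return integer.
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))
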