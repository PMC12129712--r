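#' @include AllClasses.R
NULL

#' Hashed circular fingerprint of a SMILES string
#'
#' Computes an extended-connectivity (circular) substructure fingerprint
#' of radius 2 through OpenBabel's ECFP4 implementation and folds it to
#' `nbits` bits (bitwise OR of equal halves).  The result is a
#' deterministic 0/1 vector: the same SMILES always maps to the same
#' bits, in any process.
#'
#' @param smiles a single SMILES string.
#' @param nbits fingerprint width after folding (default 2048).
#' @return integer vector of 0/1 of length `nbits`, or `NULL` when the
#'   SMILES cannot be parsed (the caller decides the rejection policy).
#' @examples
#' sum(smilesToFingerprint("c1ccccc1"))  # benzene: 3 bits set
#' @export
smilesToFingerprint <- function(smiles, nbits = 2048L) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  fp <- tryCatch({
    mol <- ChemmineOB::forEachMol("SMILES", paste0(smiles, "\tquery"),
                                  identity)
    as.numeric(ChemmineOB::fingerprint_OB(mol, "ECFP4"))
  }, error = function(e) NULL)
  if (is.null(fp) || length(fp) == 0L || sum(fp) == 0L) return(NULL)
  while (length(fp) > nbits) {
    half <- length(fp) / 2
    fp <- as.numeric(fp[seq_len(half)] | fp[half + seq_len(half)])
  }
  if (length(fp) != nbits)
    stop("native fingerprint width ", length(fp),
         " is not a power-of-two multiple of nbits = ", nbits)
  as.integer(fp)
}

#' Build a DrugSet from drug IDs and SMILES
#'
#' Fingerprints every record with [smilesToFingerprint()].  Records whose
#' SMILES cannot be parsed are dropped with a message (one bad record
#' must not abort a several-hundred-drug run); they are retained in the
#' `dropped` slot with the rejection reason.
#'
#' @param drug_ids character vector of unique identifiers.
#' @param smiles character vector of SMILES, parallel to `drug_ids`.
#' @param nbits fingerprint width (default 2048).
#' @return a [DrugSet-class].
#' @export
makeDrugSet <- function(drug_ids, smiles, nbits = 2048L) {
  stopifnot(length(drug_ids) == length(smiles),
            !anyDuplicated(drug_ids))
  fps <- lapply(smiles, smilesToFingerprint, nbits = nbits)
  bad <- vapply(fps, is.null, TRUE)
  if (any(bad))
    message(sum(bad), " drug record(s) with unparseable SMILES dropped: ",
            paste(utils::head(drug_ids[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "")
  dropped <- data.frame(drug_id = drug_ids[bad], smiles = smiles[bad],
                        reason = rep("unparseable SMILES", sum(bad)),
                        stringsAsFactors = FALSE)
  keep <- !bad
  fpm <- if (any(keep)) do.call(rbind, fps[keep]) else
    matrix(integer(0), 0, nbits)
  rownames(fpm) <- drug_ids[keep]
  new("DrugSet", drug_ids = drug_ids[keep], smiles = smiles[keep],
      fingerprints = fpm, dropped = dropped)
}

#' Read a drug table (CSV with drug_id, smiles columns) into a DrugSet
#'
#' @param path CSV path with columns `drug_id` and `smiles` (an optional
#'   `name` column is ignored).
#' @param nbits fingerprint width (default 2048).
#' @return a [DrugSet-class].
#' @export
readDrugTable <- function(path, nbits = 2048L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("drug_id", "smiles") %in% names(df)))
  makeDrugSet(as.character(df$drug_id), df$smiles, nbits = nbits)
}
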