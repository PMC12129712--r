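#' @include AllClasses.R omics.R drugs.R
NULL

#' Simulation specification
#'
#' Bundles the knobs of the synthetic-data generator.  Defaults emulate
#' the training corpus the method was built for: 38 TNBC cell lines,
#' 621 drugs, 52 metabolic pathways over a shared gene universe, with a
#' planted bilinear cell-by-drug response whose noise level leaves an
#' attainable R-squared of 0.9, and 4 planted metabolic subtypes for the
#' clustering fixtures.
#'
#' @param n_cells number of cell samples (default 38).
#' @param n_genes shared gene universe size (default 2000).
#' @param n_pathways pathway count (default 52).
#' @param pathway_size_range min/max genes per pathway (default c(20, 60)).
#' @param n_drugs drug count (default 621; capped by the packaged SMILES
#'   library).
#' @param noise_sd response noise standard deviation; `NULL` (default)
#'   derives it from `target_r2`.
#' @param target_r2 attainable (Bayes-optimal) R-squared of the planted
#'   response (default 0.9); ignored when `noise_sd` is given.
#' @param effect_channel omics channel carrying the planted signal
#'   (default `"MRNA"`).
#' @param effect_rank latent dimension of the bilinear response
#'   (default 4).
#' @param nan_fraction fraction of omics entries masked to `NA`
#'   (default 0).
#' @param planted_k cluster count for the pathway-score fixture
#'   (default 4).
#' @param separation cluster-centre spread, in units of the
#'   within-cluster noise SD, per pathway dimension (default 1; over ~50
#'   pathway dimensions this puts centres ~10 noise-SDs apart).
#' @param ic50_offset additive constant putting responses on the natural
#'   log micromolar IC50 scale (default 2.5).
#' @param seed integer seed; all generator randomness derives from it.
#' @return named list of class `"SimulationSpec"`.
#' @export
simulationSpec <- function(n_cells = 38L, n_genes = 2000L, n_pathways = 52L,
                           pathway_size_range = c(20L, 60L), n_drugs = 621L,
                           noise_sd = NULL, target_r2 = 0.9,
                           effect_channel = "MRNA", effect_rank = 4L,
                           nan_fraction = 0, planted_k = 4L,
                           separation = 1, ic50_offset = 2.5, seed = 1L) {
  stopifnot(n_cells > 0, n_genes > 0, n_pathways > 0, n_drugs > 0,
            length(pathway_size_range) == 2L,
            pathway_size_range[1] <= pathway_size_range[2],
            is.null(noise_sd) || noise_sd >= 0,
            target_r2 > 0, target_r2 <= 1,
            effect_channel %in% MODALITIES,
            nan_fraction >= 0, nan_fraction < 1, planted_k >= 2)
  if (pathway_size_range[2] > n_genes)
    stop("pathway sizes exceed the gene universe (",
         pathway_size_range[2], " > ", n_genes, ")")
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 n_pathways = as.integer(n_pathways),
                 pathway_size_range = as.integer(pathway_size_range),
                 n_drugs = as.integer(n_drugs), noise_sd = noise_sd,
                 target_r2 = target_r2, effect_channel = effect_channel,
                 effect_rank = as.integer(effect_rank),
                 nan_fraction = nan_fraction,
                 planted_k = as.integer(planted_k),
                 separation = separation, ic50_offset = ic50_offset,
                 seed = as.integer(seed)),
            class = "SimulationSpec")
}

#' Simulate the three omics matrices and a pathway map
#'
#' Draws per-modality gene values on realistic scales (CNV log2 ratios ~
#' N(0, 0.5); mRNA RMA log-intensities ~ N(6, 2); methylation beta values
#' ~ Beta(2, 2)), optionally masks a fraction of entries to `NA`, and
#' samples pathway memberships without replacement within each pathway.
#' Deterministic under the given seed.
#'
#' @param spec a [simulationSpec()].
#' @return list: `omics` (named list of three [OmicsMatrix-class]),
#'   `pathways` (a [PathwayGeneMap-class]).
#' @export
simulateOmics <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_cells; g <- spec$n_genes
  genes <- sprintf("g%04d", seq_len(g))
  cells <- sprintf("cell%03d", seq_len(n))
  dn <- list(cells, genes)
  mats <- list(
    CNV = matrix(stats::rnorm(n * g, 0, 0.5), n, g, dimnames = dn),
    MRNA = matrix(stats::rnorm(n * g, 6, 2), n, g, dimnames = dn),
    METH = matrix(stats::rbeta(n * g, 2, 2), n, g, dimnames = dn))
  if (spec$nan_fraction > 0) {
    for (m in names(mats)) {
      mask <- stats::runif(n * g) < spec$nan_fraction
      mats[[m]][mask] <- NA_real_
    }
  }
  sizes <- sample(seq(spec$pathway_size_range[1],
                      spec$pathway_size_range[2]),
                  spec$n_pathways, replace = TRUE)
  members <- lapply(sizes, function(s) sample(genes, s))
  names(members) <- sprintf("PW%02d", seq_len(spec$n_pathways))
  list(omics = lapply(names(mats),
                      function(m) OmicsMatrix(mats[[m]], m)) |>
         stats::setNames(names(mats)),
       pathways = PathwayGeneMap(members))
}

#' Simulate a drug table from the packaged SMILES library
#'
#' Samples `n_drugs` structures (without replacement when possible) from
#' the library of validated drug-like SMILES shipped with the package and
#' fingerprints them.
#'
#' @param spec a [simulationSpec()].
#' @return a [DrugSet-class].
#' @export
simulateDrugs <- function(spec) {
  lib <- utils::read.csv(system.file("extdata", "smiles_library.csv",
                                     package = "modin"),
                         stringsAsFactors = FALSE)
  set.seed(spec$seed + 1L)
  m <- spec$n_drugs
  pick <- if (m <= nrow(lib)) sample.int(nrow(lib), m)
          else sample.int(nrow(lib), m, replace = TRUE)
  makeDrugSet(sprintf("drug%04d", seq_len(m)), lib$smiles[pick])
}

#' Simulate LN_IC50 responses with a planted bilinear ground truth
#'
#' The noiseless response for cell i and drug j is `u_i' B v_j + offset`,
#' where `u_i` is a random linear summary of cell i's effect-channel
#' pathway means (computed on the L2-normalised gene vector, i.e. on
#' exactly what the model sees), `v_j` a random projection of drug j's
#' fingerprint, both standardised across the population, and `B` a random
#' rank-`effect_rank` interaction matrix.  Gaussian noise is added with
#' `noise_sd`, or with the SD that makes the attainable R-squared equal
#' `target_r2`.  The returned manifest (projections, standardisation
#' constants, noise SD, attainable ceiling) suffices to recompute every
#' noiseless response bit-exactly.
#'
#' @param sim output of [simulateOmics()].
#' @param drugs a [DrugSet-class] from [simulateDrugs()].
#' @param spec the same [simulationSpec()].
#' @return list: `pairs` (data.frame `sample_id, drug_id, ln_ic50`, full
#'   cell x drug cross), `manifest` (list).
#' @export
simulateResponses <- function(sim, drugs, spec) {
  eff <- sim$omics[[spec$effect_channel]]
  v <- omicsValues(eff)
  if (anyNA(v)) v <- omicsValues(imputeMissing(eff))
  pm <- pathwayMeans(grid_normalized(v, sim$pathways), sim$pathways)
  r <- spec$effect_rank
  set.seed(spec$seed + 2L)
  A <- matrix(stats::rnorm(r * ncol(pm), sd = 1 / sqrt(ncol(pm))), r)
  U0 <- pm %*% t(A)
  u_center <- colMeans(U0); u_scale <- apply(U0, 2L, stats::sd)
  u_scale[u_scale == 0] <- 1
  U <- sweep(sweep(U0, 2L, u_center), 2L, u_scale, "/")
  fp <- fingerprints(drugs)
  Pj <- matrix(stats::rnorm(r * ncol(fp), sd = 1 / sqrt(64)), r)
  V0 <- fp %*% t(Pj)
  v_center <- colMeans(V0); v_scale <- apply(V0, 2L, stats::sd)
  v_scale[v_scale == 0] <- 1
  V <- sweep(sweep(V0, 2L, v_center), 2L, v_scale, "/")
  B <- matrix(stats::rnorm(r * r), r)
  signal <- U %*% B %*% t(V)            # cells x drugs
  sig_var <- stats::var(as.vector(signal))
  noise_sd <- if (!is.null(spec$noise_sd)) spec$noise_sd
              else sqrt(sig_var * (1 - spec$target_r2) / spec$target_r2)
  ceiling_r2 <- sig_var / (sig_var + noise_sd^2)
  eps <- matrix(stats::rnorm(length(signal), sd = noise_sd),
                nrow(signal))
  resp <- signal + spec$ic50_offset + eps
  cells <- sampleIDs(eff)
  dr <- drugIDs(drugs)
  pairs <- data.frame(
    sample_id = rep(cells, times = length(dr)),
    drug_id = rep(dr, each = length(cells)),
    ln_ic50 = as.vector(resp), stringsAsFactors = FALSE)
  manifest <- list(effect_channel = spec$effect_channel, A = A,
                   u_center = u_center, u_scale = u_scale,
                   proj = Pj, v_center = v_center, v_scale = v_scale,
                   B = B, ic50_offset = spec$ic50_offset,
                   noise_sd = noise_sd, ceiling_r2 = ceiling_r2,
                   seed = spec$seed)
  list(pairs = pairs, manifest = manifest)
}

#' Recompute the noiseless planted response from a manifest
#'
#' @param sim output of [simulateOmics()] (same spec/seed).
#' @param drugs the matching [DrugSet-class].
#' @param manifest manifest from [simulateResponses()].
#' @return numeric matrix (cells x drugs) of noiseless responses.
#' @export
noiselessResponse <- function(sim, drugs, manifest) {
  eff <- sim$omics[[manifest$effect_channel]]
  v <- omicsValues(eff)
  if (anyNA(v)) v <- omicsValues(imputeMissing(eff))
  pm <- pathwayMeans(grid_normalized(v, sim$pathways), sim$pathways)
  U <- sweep(sweep(pm %*% t(manifest$A), 2L, manifest$u_center),
             2L, manifest$u_scale, "/")
  V <- sweep(sweep(fingerprints(drugs) %*% t(manifest$proj),
                   2L, manifest$v_center), 2L, manifest$v_scale, "/")
  U %*% manifest$B %*% t(V) + manifest$ic50_offset
}

# Scale each sample's gene vector by the L2 norm of its pathway-placed
# values (members of every pathway, duplicates counted once per
# pathway) — the same normalisation the feature grid applies, so the
# planted signal is an exact function of what the model sees.
grid_normalized <- function(values, pmap) {
  placed <- unlist(pmap@members, use.names = FALSE)
  nrm <- sqrt(rowSums(values[, placed, drop = FALSE]^2))
  nrm[nrm == 0] <- 1
  values / nrm
}

# Per-sample pathway means of a samples x genes matrix.
pathwayMeans <- function(values, pmap) {
  out <- vapply(pmap@members, function(mem)
    rowMeans(values[, mem, drop = FALSE]),
    numeric(nrow(values)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  out
}

#' Simulate a pathway-score matrix with planted subtypes
#'
#' Cluster centres are drawn i.i.d. N(0, separation^2) per pathway
#' dimension and samples receive their centre plus unit-variance Gaussian
#' noise; true labels are returned for recovery scoring.
#'
#' @param spec a [simulationSpec()] (`planted_k`, `separation`,
#'   `n_pathways`, `n_cells`, `seed`).
#' @return list: `scores` (samples x pathways matrix), `labels` (integer
#'   vector of planted subtypes).
#' @export
simulatePathwayScores <- function(spec) {
  set.seed(spec$seed + 3L)
  k <- spec$planted_k
  P <- spec$n_pathways
  n <- spec$n_cells
  centres <- matrix(stats::rnorm(k * P, sd = spec$separation), k, P)
  labels <- sort(rep_len(seq_len(k), n))
  labels <- sample(labels)             # shuffle sample-to-cluster order
  scores <- centres[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * P), n, P)
  dimnames(scores) <- list(sprintf("sample%03d", seq_len(n)),
                           sprintf("PW%02d", seq_len(P)))
  names(labels) <- rownames(scores)
  list(scores = scores, labels = labels)
}

#' Agreement between two labelings up to label permutation
#'
#' Fraction of samples on which the best one-to-one relabelling of
#' `pred` matches `truth` (computed by greedy confusion-matrix matching;
#' exact for well-separated recoveries).
#'
#' @param truth,pred integer/character label vectors of equal length.
#' @return numeric in [0, 1].
#' @export
labelAgreement <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  tab <- table(truth, pred)
  total <- 0L
  while (nrow(tab) > 0L && ncol(tab) > 0L) {
    ij <- which(tab == max(tab), arr.ind = TRUE)[1L, ]
    total <- total + tab[ij[1], ij[2]]
    tab <- tab[-ij[1], -ij[2], drop = FALSE]
  }
  as.numeric(total) / length(truth)
}

#' Write a complete simulated dataset to disk
#'
#' Emits the file set the command-line interface consumes: three omics
#' TSVs, a GMT pathway file, a drug CSV, a response CSV and a JSON
#' manifest.
#'
#' @param spec a [simulationSpec()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named list of written paths.
#' @export
writeSimulation <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateOmics(spec)
  drugs <- simulateDrugs(spec)
  resp <- simulateResponses(sim, drugs, spec)
  paths <- list()
  for (m in names(sim$omics)) {
    p <- file.path(dir, paste0(tolower(m), ".tsv"))
    v <- omicsValues(sim$omics[[m]])
    utils::write.table(data.frame(sample_id = rownames(v), v,
                                  check.names = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[m]] <- p
  }
  paths$pathways <- writePathwayGMT(sim$pathways,
                                    file.path(dir, "pathways.gmt"))
  pd <- file.path(dir, "drugs.csv")
  utils::write.csv(data.frame(drug_id = drugIDs(drugs),
                              smiles = drugs@smiles), pd,
                   row.names = FALSE, quote = FALSE)
  paths$drugs <- pd
  pr <- file.path(dir, "responses.csv")
  utils::write.csv(resp$pairs, pr, row.names = FALSE, quote = FALSE)
  paths$responses <- pr
  pm <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    c(resp$manifest[c("effect_channel", "noise_sd", "ceiling_r2",
                      "ic50_offset", "seed")],
      list(n_cells = spec$n_cells, n_drugs = spec$n_drugs)),
    pm, auto_unbox = TRUE, digits = NA)
  paths$manifest <- pm
  invisible(paths)
}
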