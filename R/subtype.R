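#' @include AllClasses.R
NULL

#' Monti-style consensus clustering of a pathway-score matrix
#'
#' For each candidate cluster number k, the samples are repeatedly
#' subsampled (fraction `subsample_fraction`, without replacement),
#' k-means is run on each subsample, and the consensus matrix entry
#' (i, j) is the fraction of co-sampled runs in which i and j landed in
#' the same cluster.  Per-k empirical CDFs over the upper-triangle
#' consensus entries (100-bin histogram), CDF areas and the relative
#' delta-area between successive k are computed, the cluster number is
#' chosen with [selectK()], and final labels per k come from
#' average-linkage hierarchical clustering of the consensus
#' dissimilarity.
#'
#' @param scores numeric matrix, samples x pathways (enrichment-score
#'   units), with row names.
#' @param k_range integer vector of candidate cluster numbers (default
#'   2:10).
#' @param resamples subsampling iterations per k (default 1000).
#' @param subsample_fraction fraction of samples per draw (default 0.8).
#' @param seed integer RNG seed.
#' @param nstart k-means restarts per run (default 10).
#' @param threshold delta-area threshold handed to [selectK()].
#' @return a [ConsensusResult-class].
#' @export
consensusCluster <- function(scores, k_range = 2:10, resamples = 1000L,
                             subsample_fraction = 0.8, seed = 42L,
                             nstart = 10L, threshold = 0.05) {
  stopifnot(is.matrix(scores), all(is.finite(scores)),
            nrow(scores) >= max(k_range) + 1L)
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("s", seq_len(nrow(scores)))
  n <- nrow(scores)
  nsub <- max(2L, floor(subsample_fraction * n))
  k_range <- sort(as.integer(k_range))
  set.seed(seed)
  consensus <- list()
  labels <- list()
  for (k in k_range) {
    co <- matrix(0, n, n)      # co-clustered counts
    tog <- matrix(0, n, n)     # co-sampled counts
    for (r in seq_len(resamples)) {
      idx <- sample.int(n, nsub)
      km <- NULL
      for (try in seq_len(5L)) {
        km <- tryCatch(
          suppressWarnings(
            stats::kmeans(scores[idx, , drop = FALSE], centers = k,
                          nstart = nstart, iter.max = 50L)),
          error = function(e) NULL)
        if (!is.null(km)) break
      }
      if (is.null(km))
        stop("k-means failed to converge after 5 restarts (k = ", k, ")")
      cl <- km$cluster
      same <- outer(cl, cl, "==") * 1
      co[idx, idx] <- co[idx, idx] + same
      tog[idx, idx] <- tog[idx, idx] + 1
    }
    cons <- ifelse(tog > 0, co / tog, 0)
    diag(cons) <- 1
    cons <- (cons + t(cons)) / 2
    dimnames(cons) <- list(rownames(scores), rownames(scores))
    consensus[[as.character(k)]] <- cons
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
    lab <- stats::cutree(hc, k = k)
    labels[[as.character(k)]] <- lab
  }
  cdfs <- lapply(consensus, consensusCDF)
  areas <- vapply(cdfs, function(cdf) sum(cdf) * 0.01, numeric(1))
  delta <- numeric(length(k_range))
  delta[1] <- areas[1]
  if (length(k_range) > 1L)
    delta[-1] <- diff(areas) / utils::head(areas, -1L)
  names(delta) <- as.character(k_range)
  res <- new("ConsensusResult", k_values = k_range, consensus = consensus,
             cdf = cdfs, area = stats::setNames(areas, names(delta)),
             delta_area = delta, chosen_k = k_range[1], labels = labels)
  res@chosen_k <- selectK(res, threshold = threshold)
  res
}

# Empirical CDF of the upper-triangle consensus entries, evaluated at the
# right edges of 100 equal bins on [0, 1].
consensusCDF <- function(cons) {
  x <- cons[upper.tri(cons)]
  edges <- seq_len(100L) / 100
  vapply(edges, function(t) mean(x <= t), numeric(1))
}

#' Choose the cluster number from the delta-area curve
#'
#' Returns the smallest k whose successor's relative delta-area falls
#' below `threshold` — the point where adding another cluster no longer
#' improves consensus stability appreciably.  If no k qualifies, the
#' largest k is returned with a warning.
#'
#' The delta-area vector follows the usual convention: `delta[k]` is the
#' relative gain in CDF area of k over k-1 (for the smallest k it is the
#' area itself), so the chosen k is the one whose *successor* brings an
#' insignificant gain.
#'
#' @param result a [ConsensusResult-class].
#' @param threshold relative delta-area cutoff (default 0.05).
#' @return integer, the chosen k.
#' @export
selectK <- function(result, threshold = 0.05) {
  kv <- result@k_values
  delta <- result@delta_area
  if (length(kv) < 2L) return(kv[1])
  for (i in seq_len(length(kv) - 1L)) {
    if (delta[i + 1L] < threshold) return(kv[i])
  }
  warning("no k has a sub-threshold successor delta-area; returning max k")
  kv[length(kv)]
}

#' Compare predicted drug sensitivity between two subtype groups
#'
#' For every drug, compares the predicted LN_IC50 distributions of two
#' sample groups with the two-sample Kolmogorov-Smirnov test and Welch's
#' unequal-variance t test.  When both groups are degenerate (all values
#' identical) the KS statistic is still computed but the t statistic is
#' `NaN`.
#'
#' @param predictions data.frame `sample_id, drug_id, ln_ic50_pred` (long
#'   format, as from [predictPairs()]).
#' @param labels named vector of group labels (names = sample IDs).
#' @param pair length-2 vector naming the two groups to compare.
#' @return data.frame `drug_id, group_a, group_b, ks_stat, ks_p, t_stat,
#'   t_p`, one row per drug.
#' @export
compareGroups <- function(predictions, labels, pair) {
  stopifnot(length(pair) == 2L,
            all(c("sample_id", "drug_id", "ln_ic50_pred") %in%
                  names(predictions)))
  ga <- names(labels)[labels == pair[1]]
  gb <- names(labels)[labels == pair[2]]
  if (length(ga) < 2L || length(gb) < 2L)
    stop("each group needs at least 2 samples (", pair[1], ": ",
         length(ga), ", ", pair[2], ": ", length(gb), ")")
  out <- lapply(split(predictions, predictions$drug_id), function(df) {
    xa <- df$ln_ic50_pred[df$sample_id %in% ga]
    xb <- df$ln_ic50_pred[df$sample_id %in% gb]
    ks <- suppressWarnings(stats::ks.test(xa, xb))
    tt <- if (stats::sd(xa) == 0 && stats::sd(xb) == 0)
      list(statistic = NaN, p.value = NaN)
    else suppressWarnings(stats::t.test(xa, xb, var.equal = FALSE))
    data.frame(drug_id = df$drug_id[1], group_a = pair[1],
               group_b = pair[2],
               ks_stat = unname(ks$statistic), ks_p = ks$p.value,
               t_stat = unname(tt$statistic), t_p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' All pairwise subtype comparisons
#'
#' Runs [compareGroups()] for every unordered pair of groups present in
#' `labels` (C(k, 2) tables, concatenated).
#'
#' @inheritParams compareGroups
#' @return long data.frame, rows = drugs x group pairs.
#' @export
compareAllGroups <- function(predictions, labels) {
  gs <- sort(unique(labels))
  combs <- utils::combn(gs, 2L, simplify = FALSE)
  do.call(rbind, lapply(combs, function(pr)
    compareGroups(predictions, labels, pr)))
}
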