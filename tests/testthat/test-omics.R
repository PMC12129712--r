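test_that("gene intersection keeps exactly the concurrently measured genes", {
  mk <- function(genes, mod) {
    OmicsMatrix(matrix(seq_along(genes), 1, length(genes),
                       dimnames = list("s1", genes)), mod)
  }
  om <- list(mk(c("A", "B", "C"), "CNV"), mk(c("B", "C", "D"), "MRNA"),
             mk(c("B", "C"), "METH"))
  ix <- intersectGenes(om)
  expect_identical(ix$genes, c("B", "C"))
  for (m in ix$matrices) expect_identical(geneIDs(m), c("B", "C"))

  # identical gene lists: identity subset (sorted order)
  om2 <- tiny_omics()
  ix2 <- intersectGenes(om2)
  expect_identical(ix2$genes, sort(geneIDs(om2$CNV)))
  expect_equal(omicsValues(ix2$matrices$MRNA),
               omicsValues(om2$MRNA)[, ix2$genes])
})

test_that("intersection size matches an independent set computation", {
  set.seed(42)
  universe <- sprintf("G%03d", 1:500)
  shared <- sample(universe, 400)
  gene_sets <- lapply(1:3, function(i)
    sample(c(shared, sample(setdiff(universe, shared), 30))))
  samples <- paste0("s", 1:10)
  om <- Map(function(g, mod) {
    OmicsMatrix(matrix(rnorm(10 * length(g)), 10, length(g),
                       dimnames = list(samples, g)), mod)
  }, gene_sets, c("CNV", "MRNA", "METH"))
  # independent oracle: plain Reduce/intersect on the raw name vectors
  oracle <- length(Reduce(intersect, gene_sets))
  ix <- intersectGenes(om)
  expect_identical(length(ix$genes), oracle)
  expect_identical(ncol(omicsValues(ix$matrices[[1]])), oracle)
})

test_that("intersection fails loudly on sample mismatch or empty overlap", {
  om <- tiny_omics()
  bad <- om$MRNA
  rownames(bad@values)[1] <- "intruder"
  expect_error(intersectGenes(list(om$CNV, bad, om$METH)), "intruder")

  g2 <- tiny_omics(genes = paste0("h", 1:6))
  expect_error(intersectGenes(list(om$CNV, g2$MRNA, om$METH)),
               "no genes")
})

test_that("mean imputation fills NAs with per-gene means and flags extremes", {
  m <- matrix(c(1, NA, 3, 5, 5, 5), 3, 2,
              dimnames = list(paste0("s", 1:3), c("gA", "gB")))
  out <- imputeMissing(OmicsMatrix(m, "MRNA"))
  expect_equal(omicsValues(out)[, "gA"], c(s1 = 1, s2 = 2, s3 = 3))
  expect_equal(omicsValues(out)[, "gB"], c(s1 = 5, s2 = 5, s3 = 5))

  expect_identical(imputeMissing(m[, 2, drop = FALSE]),
                   m[, 2, drop = FALSE])  # no NA: unchanged

  allmiss <- matrix(NA_real_, 3, 1, dimnames = list(paste0("s", 1:3), "gX"))
  expect_warning(out2 <- imputeMissing(allmiss), "entirely missing")
  expect_true(all(out2 == 0))
})

test_that("imputation matches a loop-based oracle and preserves present values", {
  set.seed(7)
  v <- matrix(rnorm(160), 20, 8,
              dimnames = list(paste0("s", 1:20), paste0("g", 1:8)))
  v[sample(length(v), 40)] <- NA
  v[, 3] <- NA; v[1:2, 3] <- c(1, 2)   # a >50%-missing gene
  oracle <- v
  for (j in seq_len(ncol(oracle))) {
    mu <- mean(oracle[, j], na.rm = TRUE)
    for (i in seq_len(nrow(oracle)))
      if (is.na(oracle[i, j])) oracle[i, j] <- mu
  }
  suppressMessages(out <- imputeMissing(v))
  expect_equal(out, oracle)
  present <- !is.na(v)
  expect_identical(out[present], v[present])
})

test_that("p-norm normalisation matches closed forms and is idempotent", {
  expect_equal(pnormNormalize(c(3, 4)), c(0.6, 0.8))
  expect_equal(pnormNormalize(rep(1, 4), p = 1), rep(0.25, 4))
  set.seed(1)
  x <- rnorm(100)
  n1 <- pnormNormalize(x)
  expect_equal(sqrt(sum(n1^2)), 1, tolerance = 1e-9)
  expect_equal(pnormNormalize(n1), n1, tolerance = 1e-9)
  n2 <- pnormNormalize(x, p = 1)
  expect_equal(sum(abs(n2)), 1, tolerance = 1e-9)
  expect_warning(z <- pnormNormalize(numeric(3)), "zero vector")
  expect_identical(z, numeric(3))
})

test_that("grid assembly places normalised values at pathway slots with zero padding", {
  om <- tiny_omics(n = 1)
  pmap <- tiny_pmap()
  gs <- assembleGrid(om, pmap)
  expect_identical(dim(gs@grid), c(1L, 3L, 2L, 3L))
  expect_identical(gs@grid[1, , 1, 3], c(0, 0, 0))  # pwA pad slot
  expect_true(gs@pad_mask[1, 3])
  expect_false(any(gs@pad_mask[2, ]))

  # all-equal values: every non-pad slot is the constant / the norm of
  # the 5 pathway-placed values, i.e. 1/sqrt(5)
  cm <- matrix(2, 2, 6, dimnames = list(c("s1", "s2"), paste0("g", 1:6)))
  omc <- list(CNV = OmicsMatrix(cm, "CNV"))
  gsc <- assembleGrid(omc, pmap)
  expect_equal(gsc@grid[1, 1, 1, 1], 1 / sqrt(5))
  # non-pad entries of a sample/channel plane now have unit L2 norm
  expect_equal(sqrt(sum(gsc@grid[1, 1, , ][!gsc@pad_mask]^2)), 1,
               tolerance = 1e-9)
})

test_that("grid entries match an index-by-index lookup oracle", {
  set.seed(3)
  genes <- paste0("g", 1:30)
  om <- tiny_omics(n = 10, genes = genes, seed = 3)
  pmap <- PathwayGeneMap(list(p1 = genes[c(3, 9, 1)],
                              p2 = genes[c(10, 20, 30, 5)],
                              p3 = genes[15]))
  gs <- assembleGrid(om, pmap, p = 2)
  mods <- names(om)
  placed <- unlist(pathwayMembers(pmap), use.names = FALSE)
  for (b in c(1, 4, 10)) for (ci in 1:3) {
    raw <- omicsValues(om[[mods[ci]]])[b, ]
    nrm <- sqrt(sum(raw[placed]^2))
    for (q in 1:3) {
      mem <- pathwayMembers(pmap)[[q]]
      for (j in seq_along(mem))
        expect_equal(gs@grid[b, ci, q, j], raw[[mem[j]]] / nrm)
    }
  }
  # losslessness: raw value = grid value * stored norm
  expect_equal(gs@grid[2, 1, 1, 1] * gs@norms[2, 1],
               unname(omicsValues(om$CNV)[2, "g3"]))
})

test_that("permuting sample order permutes grids identically", {
  om <- tiny_omics(n = 5)
  pmap <- tiny_pmap()
  g1 <- assembleGrid(om, pmap)
  perm <- c(3, 1, 5, 2, 4)
  omp <- lapply(om, function(m)
    OmicsMatrix(omicsValues(m)[perm, ], modality(m)))
  g2 <- assembleGrid(omp, pmap)
  expect_equal(g2@grid, g1@grid[perm, , , , drop = FALSE])
  expect_identical(sampleIDs(g2), sampleIDs(g1)[perm])
})

test_that("grid assembly rejects pathways referencing absent genes", {
  om <- tiny_omics()
  pmap <- PathwayGeneMap(list(bad = c("g1", "nosuchgene")))
  expect_error(assembleGrid(om, pmap), "nosuchgene")
})

test_that("GMT and omics files round-trip through the readers", {
  dir <- withr::local_tempdir()
  pmap <- tiny_pmap()
  writePathwayGMT(pmap, file.path(dir, "p.gmt"))
  back <- readPathwayGMT(file.path(dir, "p.gmt"))
  expect_identical(pathwayMembers(back), pathwayMembers(pmap))

  om <- tiny_omics(n = 3)
  v <- omicsValues(om$CNV)
  write.table(data.frame(sample_id = rownames(v), v, check.names = FALSE),
              file.path(dir, "cnv.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  rd <- readOmicsMatrix(file.path(dir, "cnv.tsv"), "CNV")
  expect_equal(omicsValues(rd), v)
  expect_identical(modality(rd), "CNV")
})
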