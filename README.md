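# modin

Multi-omics drug–cell interaction network for LN_IC50 drug-sensitivity
prediction and metabolic subtyping.

## What it does, and for whom

Drug screens such as GDSC report the natural-log IC50 (µM) of hundreds
of compounds against panels of cancer cell lines.  `modin` is for
computational biologists who want to (i) learn a regression from
pathway-structured multi-omics cell profiles plus drug structures onto
that LN_IC50 surface, (ii) apply it to new samples (e.g. patient
cohorts), and (iii) stratify a cohort into metabolic subtypes and ask
which drugs separate them.

The model, in the field's standard notation:

* **Cell side** — per sample, the CNV / mRNA / methylation vectors over
  the shared gene set are unit p-norm normalised and arranged as a
  3-channel pathway × gene-slot image `X ∈ ℝ^{3×P×G}`; a stacked CNN
  (Conv–BatchNorm–ReLU ×2, max-pool, linear) yields `H1 ∈ ℝ^{d1}`.
* **Drug side** — the SMILES is hashed to a radius-2 circular
  (ECFP4-type) 2048-bit fingerprint `h`; an MLP yields `H2 ∈ ℝ^{d2}`.
* **Interaction** — multi-head cross-modal attention with
  `K = W_k H1 + b_k`, `V = W_v H1 + b_v`, `Q = W_q H2 + b_q`,
  `A = softmax(QKᵀ/√d_k) V` per head, heads concatenated and mapped
  linearly to the scalar prediction `ŷ = LN_IC50`.
* **Training** — MSE loss, Adam, drug-stratified 80/20 splits over
  several seeds; metrics MSE, RMSE = √MSE, R² = 1 − MSE/Var(y),
  Pearson r.
* **Subtyping** — Monti consensus clustering (resampled k-means) of a
  pathway enrichment-score matrix, optimal k from the CDF delta-area
  curve, then per-drug Kolmogorov–Smirnov and Welch t tests between
  subtypes.

A seeded synthetic-data generator (`simulationSpec`, `simulateOmics`,
`simulateDrugs`, `simulateResponses`, `simulatePathwayScores`) emulates
all inputs with a planted bilinear ground truth, so the whole pipeline
is testable offline.

## Worked example

```r
library(modin)

spec  <- simulationSpec(n_cells = 20, n_genes = 200, n_pathways = 6,
                        pathway_size_range = c(5, 10), n_drugs = 40,
                        target_r2 = 0.9, seed = 1)
sim   <- simulateOmics(spec)
drugs <- simulateDrugs(spec)
resp  <- simulateResponses(sim, drugs, spec)
grids <- assembleGrid(sim$omics, sim$pathways)
grids
#> CellGridSet: 20 cells, 3 channel(s) [CNV,MRNA,METH], 6 pathways x 10 slots (L2-normalised)
drugs
#> DrugSet: 40 drugs, 2048-bit fingerprints (0 record(s) dropped)

cfg <- modinConfig(channels = 3, P = 6, G = padWidth(sim$pathways),
                   kernel_size = 3, conv_channels = c(8, 8), d1 = 64,
                   mlp_hidden = 64, d2 = 64, latent_dim = 32, heads = 4)
sp  <- splitPairs(resp$pairs, seed = 42)
fit <- trainModin(grids, drugs, sp$train, cfg, epochs = 80,
                  batch_size = 64, seed = 42)
met <- evaluateModel(fit$model, grids, drugs, sp$test)
#> test MSE 4.399  RMSE 2.097  R2 0.685  Pearson 0.835  (ceiling R2 0.90)
```

The generator's manifest records the attainable (Bayes-optimal) R² of
0.90 — the noise floor of the planted response; the model explains 0.685
of the held-out variance after a deliberately short 80-epoch run, and
`predictPairs(fit$model, grids, drugs, pairs)` returns predictions in
input order:

```r
head(predictPairs(fit$model, grids, drugs, resp$pairs[, 1:2]), 3)
#>   sample_id  drug_id ln_ic50_pred
#> 1   cell001 drug0001    1.9554256
#> 2   cell002 drug0001    0.2777104
#> 3   cell003 drug0001    2.9331025
```

For subtyping:

```r
ps  <- simulatePathwayScores(simulationSpec(n_cells = 120, n_pathways = 52,
                                            planted_k = 4, seed = 7))
res <- consensusCluster(ps$scores, k_range = 2:6, resamples = 100, seed = 42)
chosenK(res)                                   # 4
tab <- compareAllGroups(preds, clusterLabels(res))   # KS + Welch t per drug
```

A thin command-line wrapper over these functions ships in
`inst/scripts/modin.R` (`simulate`, `train`, `predict`, `ablate`,
`subtype` subcommands).

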