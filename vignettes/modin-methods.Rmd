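---
title: "Pathway-structured multi-omics drug-response prediction with modin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-structured multi-omics drug-response prediction with modin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Drug-sensitivity screens report, for a panel of cell lines and a library
of compounds, the natural-log IC50 (µM) at which each compound inhibits
each line.  `modin` learns a regression from two very different inputs
onto that LN_IC50 surface: on the cell side, three omics modalities (copy
number log2 ratios, RMA-normalised mRNA expression, and methylation beta
values) organised by metabolic pathway; on the drug side, the molecular
structure given as a SMILES string.  The package also covers the cohort
analysis built on top of such a model: consensus clustering of pathway
enrichment scores into metabolic subtypes and per-drug comparison of
predicted sensitivities between subtypes.

## The model

**Cell-line extractor.**  For each sample, the three omics vectors over
the shared gene set are each normalised to unit p-norm (default L2; L1
available via `norm_p`) and laid out on a `3 × P × G` grid: one channel
per modality, one row per pathway, one column per gene slot, rows padded
with zeros to the largest pathway size `G`.  A stacked CNN —
Conv→BatchNorm→ReLU, twice, then 2×2 max pooling, flattening, and a
linear head — maps the grid to a `d1`-dimensional embedding `H1`.  Two
points are deliberate design choices:

* *Per-sample grids.*  A literal reading of the source architecture
  convolves a single `3 × N × d0` image in which the height axis is the
  *sample* axis, so convolution would mix information across cell lines
  and break single-patient inference.  `modin` instead gives every
  sample its own pathway×gene image; the channel stacking and 2-D
  convolution are preserved.
* *Masked padding.*  Pathways are ragged; padded slots are zero on
  input, and activations at pad positions are re-zeroed between layers
  so that padding stays inert through the whole stack.  This makes
  embeddings exactly invariant to appending further pad columns, a
  property the test suite asserts.

**Drug extractor.**  SMILES are fingerprinted with radius-2
extended-connectivity (circular) hashing — OpenBabel's ECFP4, folded by
bitwise OR to 2048 bits — and passed through an MLP (default
2048→512→`d2`, ReLU on hidden layers) to a dense embedding `H2`.
Unparseable SMILES are dropped with a logged reason rather than aborting
a several-hundred-drug run.

**Cross-modal attention.**  Key and Value are linear projections of the
cell embedding and the Query of the drug embedding (the equations of the
source method; its figure caption states the transposed arrangement,
which remains available as `attention_direction = "cell_query"`).  Each
embedding is reshaped into `tokens_per_modality` tokens (default 4) so
the soft-max is not degenerate; per head, attention is
`softmax(QKᵀ/√d_k)V`, heads are concatenated, and a final linear layer
yields the scalar LN_IC50 prediction.  Training minimises MSE with Adam
(lr 0.001, batch 32, 1000 epochs in the reference protocol; all three
are configurable), under a drug-stratified 80/20 split repeated over
seeds 42, 1234, 2023, 3407 and 619 with metrics averaged
(`multiSeedRun`).

**Metrics.**  `computeMetrics` reports MSE, RMSE = √MSE, R² = 1 −
MSE/Var(y), and Pearson's r.  R² of a zero-variance truth vector is
undefined and reported as `NaN` with a warning.

## Subtype discovery

`consensusCluster` implements Monti-style consensus clustering: for each
candidate k (default 2–10) the samples are subsampled 1000 times at
fraction 0.8, k-means (10 restarts) is run per draw, and consensus(i, j)
is the co-clustering rate among co-sampled draws.  The per-k empirical
CDF of the upper-triangle consensus entries uses 100 bins; `selectK`
picks the smallest k whose successor adds a relative CDF-area gain below
0.05 — the threshold is declared, since "insignificant increase" has no
published value, and the point of the delta-area curve is precisely that
the choice should be insensitive to it near the plateau.  Final labels
come from average-linkage hierarchical clustering of 1 − consensus.
`compareGroups` then contrasts predicted LN_IC50 distributions between
subtypes per drug with the two-sample Kolmogorov–Smirnov test and
Welch's t test (unequal variances, since subtype variances have no
reason to match); p-values are reported raw, as the downstream heatmaps
expect, with Benjamini–Hochberg left to the caller via `p.adjust`.

## The synthetic-data generator

Every fixture is generated in code, seeded, and ships with an analytic
yardstick:

* **Omics**: CNV ~ N(0, 0.5), mRNA ~ N(6, 2), methylation ~ Beta(2, 2);
  optional missingness; pathway memberships drawn without replacement.
* **Drugs**: sampled from a packaged library of 720 validated drug-like
  SMILES, so no network access is ever needed.
* **Responses**: `ln_ic50(i, j) = u_iᵀ B v_j + offset + ε`, with `u_i` a
  random linear summary of cell i's effect-channel pathway means
  (computed on the normalised gene vector — exactly what the model
  sees), `v_j` a random projection of drug j's fingerprint, both
  standardised, and `B` a small random interaction matrix.  The response
  is deliberately *bilinear*, not attention-shaped: recovery tests must
  not assume the model family is correctly specified.  Noise is set so
  the attainable R² is 0.9 by default; the manifest records every
  projection so the noiseless surface is recomputable bit-exactly.
* **Pathway scores**: planted k clusters with centres ~ N(0, separation²)
  per dimension and unit within-cluster noise.  With the default
  separation 1 and ~50 pathway dimensions, centres sit about 10
  within-cluster SDs apart.

What the generator does **not** emulate: dose–response curve artefacts,
batch effects across platforms, gene–gene correlation structure, or the
chemical coherence of a real compound library.  Passing tests therefore
demonstrate that the implementation is correct and that the architecture
can recover a planted cross-modal signal — not that the published
benchmark numbers transfer to new cohorts.

## Desk-scale protocol and numerical choices

The reference-scale run (38 lines × 621 drugs, 25×25 kernels, 512-wide
layers, 1000 epochs) needs a GPU and the external screen download; it is
scripted but not part of the test suite.  The test suite and the
acceptance script instead use a desk-scale study: 30 cells × 80 drugs
(2400 pairs), 8 pathways of 6–12 genes, 3×3 kernels, 8-channel
convolutions, 64-wide embeddings, latent width 32 with 4 heads and 4
tokens, 200 training epochs at batch 96 — sizes chosen so a full
recovery run completes in minutes on one CPU while leaving the planted
signal (ceiling R² 0.9) clearly recoverable (test R² ≥ 0.6) and a
permuted-label control clearly not (R² ≤ 0.1).

**What the omics ablation can and cannot show.**  Under the standard
pair-level 80/20 split every cell line appears in training, and a
per-cell encoder can identify a cell from *any* channel's unique pattern
— the omics values act as a fingerprint — and memorise that cell's
response coefficients.  On the planted fixture this makes all seven
channel subsets score within noise of each other (R² ≈ 0.71–0.76 at 60
epochs) even though the generator puts signal only in the mRNA channel;
notably, the reference benchmark's own ablation table shows the same
compressed spread (R² 0.8026–0.8254).  Evaluating on held-out cells
(`runAblation(..., holdout = "cell")`) removes the shortcut, but at the
desk-scale cohort of 30 cells the deep model then fails to transfer for
every subset: two dozen training samples are too few for it to prefer
the generalising linear map over memorisation.  The ablation harness is
therefore an honest measurement device, but on small cohorts its
pair-level numbers reflect cell-identity capacity more than channel
informativeness, and a planted-signal ordering should not be expected
from it; the corresponding end-to-end check in the test suite documents
this by failing.

Other numerics: He/Xavier initialisation under the run seed; batch-norm
uses minibatch statistics in training and running averages (momentum
0.1, eps 1e-5) in eval, stated explicitly because tiny cohorts make
batch statistics noisy; convolution bias gradients are identically zero
under batch-norm (the optimiser simply leaves them); zero vectors are
returned unchanged by p-norm normalisation with a warning; a drug with
a single labelled pair cannot be split and goes to the training set with
a warning; k-means inside the consensus loop is retried up to five times
on failure.  Backward passes are validated against central finite
differences, and the convolution, MLP, attention and KS statistics
against naive loop-based oracles, in `tests/testthat/`.

## Known limitations

* The published GDSC benchmark values (R² 0.8254, MSE 0.9672, RMSE
  0.9835, Pearson 0.96) are reproducible only with the external
  download and reference-scale training; the package verifies their
  internal identities (√0.9672 = 0.9835; the 12.31% gain over the
  strongest baseline) and the pipeline's behaviour on synthetic data.
* Attention-weight interpretability exports and graph-based drug
  encoders are out of scope.
* GSVA/ssGSEA enrichment scoring is consumed, not computed: feed
  `consensusCluster` a precomputed score matrix or the synthetic one.
* Survival analysis over subtypes (Kaplan–Meier, log-rank) is routine
  downstream work left to `survival`.
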