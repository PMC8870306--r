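---
title: "Classifying NPI levels from multi-omics GSN maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying NPI levels from multi-omics GSN maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

The Nottingham Prognostic Index (NPI) summarizes breast-cancer prognosis
after surgery as

\[
\mathrm{NPI} = 0.2 \, S + N + G,
\]

where \(S\) is the tumor size in centimeters, \(N\) the nodal-status category
(0 nodes = 1, 1–3 nodes = 2, more than 3 nodes = 3) and \(G\) the histologic
grade (1–3). Scores bin into four levels with decreasing five-year survival:
level I (2.0–2.4), II (2.4–3.4], III (3.4–5.4] and IV (> 5.4). `gsnpi`
implements a pipeline that predicts these levels from three omics layers —
gene expression, copy-number alteration (CNA) and mRNA — by turning each
sample's omics profile into a small image and training a convolutional
classifier on those images:

1. **Complete-case alignment.** The three gene-by-sample matrices and the
   clinical table are restricted to their shared samples with no missing
   omics value and no missing \(S\), \(N\) or \(G\).
2. **Hybrid feature selection**, per omic. A *summed-expression chi-square*
   ranker scores each gene by \(\chi^2_j = \sum_c (O_{jc}-E_{jc})^2/E_{jc}\)
   with \(O_{jc} = \sum_{i \in c} x_{ij}\) the class-wise sum and
   \(E_{jc} = (n_c/N)\sum_i x_{ij}\) its size-proportional expectation; the
   top-k genes feed a mutual-information mRMR ranking (greedy
   relevance-minus-redundancy), and a random-forest forward search over
   ranking prefixes under stratified cross-validation picks the final subset.
3. **GSN template.** The selected genes — each one a point in sample space —
   are embedded in 2-D by exact t-SNE (Gaussian affinities symmetrized as
   \(p_{ij} = (p_{i|j}+p_{j|i})/2n\), Student-t low-dimensional kernel,
   KL-divergence gradient descent) or by a Kohonen self-organizing map, then
   rasterized to a g-by-g grid with one pixel per gene (the *gene similarity
   network* template).
4. **Map rendering.** Omics values are log-transformed (CNA excepted) and
   z-scored per gene; each sample colors the template. *Merged* mode makes a
   3-channel image (R = expression, G = CNA, B = mRNA on one shared
   template); *concatenated* mode makes one single-channel map per omic on
   per-omic templates.
5. **Augmentation.** Elastic deformation (smoothed random displacement
   fields, alpha 15–18) balances the training classes.
6. **Classification.** VGG- and ResNet-style networks (7×7 kernels, stride 1,
   swish activations, per-layer batch normalization; residual blocks of 4 or
   5 convolutions with identity or 1×1 mapping shortcuts, stride 2 where a
   block downsamples) trained with categorical cross-entropy; softmax
   probabilities, top-1 accuracy and macro one-vs-rest AUC are reported. The
   concatenated variant runs one branch per omic and joins the pooled
   features before a shared softmax head.
7. **Survival validation.** Kaplan–Meier relapse-free curves per NPI level
   (via `survival::survfit`) confirm that the levels order survival as the
   index intends.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `top_k` (ranker cut) | 1000 (pipeline uses 50 of 500 synthetic genes) | genes | keeps the mRMR step tractable; proportionally mirrors a 1000-of-16k cut |
| `max_subset` (wrapper) | 30 (pipeline: 15) | genes | realistic selected-panel sizes are tens of genes |
| `folds` | 5 | — | stratified CV for the forward search |
| MI `bins` | 10 | quantile bins | equal-frequency binning is robust to the heavy tails of expression data |
| t-SNE `perplexity` | `min(5, genes − 1)` | effective neighbors | selected panels are small (≈ 10–30 genes) |
| t-SNE `iterations` | 1000 | — | ample for ≤ 50 points |
| t-SNE `learning_rate` | `n/12` | — | the standard heuristic; fixed rates sized for thousands of points tear apart tight duplicates at n ≈ 30 |
| SOM grid, epochs | ⌈√genes⌉², 200 | neurons, passes | one neuron per gene on average |
| template `grid_size` g | 32 (16 in tests) | pixels | holds tens of genes with room for collision resolution |
| `pseudocount`, `log_base` | 1, 2 | — | log2(x+1), the usual expression transform |
| `clip_sigma` | 3 | z-score units | ±3 sd covers ≈ 99.7% of values; the linear map to [0,1] saturates outside |
| elastic `alpha` | drawn U(15, 18) | display pixels | conventional magnitudes for ≈ 224-px images; displacements rescale by g/224 so the same alphas stay meaningful on small maps |
| elastic `sigma` | g/8 | pixels | smooth, low-frequency warps |
| `epochs`, `batch_size`, lr | 20, 32, 1e-3 | — | Adam; enough to converge on strongly separable maps |
| `validation_fraction` | 0.2 | — | stratified 80/20 split |
| `n_classes` | 4 | — | the four NPI levels; configurable (a 5-class head is accepted for compatibility with conventions that add an output slot) |

## The synthetic cohort: what it emulates and what it does not

`simulate_clinical()` draws tumor sizes (lognormal), node counts (negative
binomial) and grades (categorical) and **derives** each sample's NPI score
and level from them — labels are never assigned directly, so the
label-consistency invariant (`npi_level(compute_npi(...))` equals the stored
level) holds by construction. Rejection sampling fills per-level quotas
(balanced by default) to keep all four classes testable. Relapse-free times
are exponential with strictly decreasing level means (130/110/80/45 months)
and 30% right-censoring, reproducing the qualitative survival ordering of
the levels without claiming any real cohort's month values.

`simulate_multiomics()` plants `n_informative = 10` of 500 genes whose
expression log-mean shifts by `(level − 1) × effect_size` (default 2); the
mRNA layer repeats the informative expression with lognormal noise (additive
Gaussian noise on the raw scale could produce negative abundances, which the
chi-square ranker must reject), and the CNA layer tilts its −2…2 state
probabilities toward gains with level. The generator does **not** emulate
linkage or copy-number segment structure, batch effects, or realistic
correlation among background genes — so a passing pipeline demonstrates that
the machinery recovers planted multi-omics signal end-to-end, not that it
would reach comparable accuracy on a real cohort.

Default problem sizes (400 samples, 500 genes, 10 informative, g = 32,
reduced ResNet, 20 epochs) are the package's study conditions; the test
suite's smoke runs use smaller cohorts (120 samples, 80 genes, g = 16,
3 epochs) for brevity.

## Numerical and design choices

* **Chi-square on non-negative values.** \(E_{jc}\) in the denominator is
  meaningless for signed data, so the ranker requires non-negative input and
  offers a per-gene minimum shift (`shift = TRUE`) for the CNA layer.
  All-zero genes get \(\chi^2 = 0\) and a degenerate flag.
* **mRMR criterion.** The difference (MID) form
  \(I(x_j,c) - |S|^{-1}\sum_{i \in S} I(x_j,x_i)\) is the default; the
  quotient (MIQ) form is available. All ties — here and everywhere — break
  lexicographically by gene id, making rankings deterministic.
* **Genes, not samples, are embedded.** The template must be shared across
  samples and colored per sample, which forces the embedded objects to be
  genes (points in sample space, Euclidean distance). Correlation-based
  distances are a one-line preprocessing step away (standardize the rows)
  but are not the default.
* **Template collisions.** Coordinates are min-max scaled to the grid and
  rounded; a deterministic spiral search (squared distance, then row, then
  column) moves colliding genes to the nearest free pixel, ordered by
  embedded coordinate then gene id. Injectivity is property-tested.
* **Pre-activation residual blocks.** Batch normalization and swish live
  inside the residual branch and the block output is the bare sum
  \(H(x) = F(x) + x\). Zeroing the branch therefore yields the identity map
  exactly — the identity limit the residual formulation promises, and a
  diagnostic (`resblock_identity_gap()`) measures it.
* **Layer counting.** Convolutions, dense layers and mapping-shortcut
  convolutions count; batch norm, activations, pooling and flatten do not.
  The full ResNet preset reaches exactly 112 counted layers (stem + 3 ×
  [four 4-conv mapped blocks + one 5-conv identity block] + seven 4-conv
  mapped blocks + dense head) and the full VGG preset 33 (5 × 6 convolutions
  + 3 dense). The block prose underdetermines the arithmetic, so the presets
  are defined by this documented convention. Reduced presets keep the block
  grammar (the reduced ResNet's stem convolution uses stride 2 at g ≥ 32) at
  desk scale.
* **Softmax over classes.** The classification head always normalizes over
  the class dimension; conventions that describe the normalization count as
  a feature count are not followed.
* **Augment after splitting.** Elastic copies are created only from training
  images, never validation ones — augmenting before the split would leak
  warped copies of validation samples into training.
* **Background and transfer.** Non-template pixels are 0; z-scores map
  linearly from ±`clip_sigma` to [0, 1] (so z = 0 renders mid-gray, 0.5).
  Images are kept as raw g×g arrays for training; PNG export (8-bit,
  nearest-neighbor upscale) is presentation-only.
* **Cross-omic gene mismatches.** Gene sets need not match across omics at
  load time. Merged-mode templates are built from the expression layer's
  selected genes; genes absent from another layer are dropped with a warning
  before template construction, and rendering errors if a template gene is
  missing from a layer.
* **Determinism.** Every stochastic stage derives its seed from the master
  seed and the stage name; fixed seeds give bit-identical embeddings, maps,
  and training histories.

## Known limitations

* The CNN engine is a compact, pure-R implementation (im2col convolutions,
  BLAS matmuls) built for small GSN maps; it is not a general-purpose
  deep-learning framework, and the full 112/33-layer presets are provided as
  architecture specifications for auditing depth and structure rather than
  for desk-scale training.
* Macro one-vs-rest AUC is one of several multi-class AUC definitions;
  values are comparable within this package, not across averaging schemes.
* The Kaplan–Meier stage estimates curves per level; between-level testing
  (log-rank) is intentionally out of scope.
* Real-cohort performance claims require real cohorts; see the synthetic
  generator's caveats above.
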