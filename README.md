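# gsnpi — multi-omics GSN maps for Nottingham Prognostic Index classification

`gsnpi` predicts the Nottingham Prognostic Index (NPI) level of breast-cancer
samples from three omics layers — gene expression, copy-number alteration
(CNA) and mRNA — by turning each sample's omics profile into a small image
and training a convolutional classifier on those images. It is aimed at
computational-biology groups who want a tested, fully seeded reference
implementation of the tabular-omics-to-image approach: hybrid feature
selection, gene-similarity-network (GSN) embedding, per-sample map rendering,
elastic augmentation, compact VGG/ResNet classifiers, plus NPI scoring and
Kaplan–Meier survival validation.

## The method

The NPI combines tumor size *S* (cm), nodal status *N* (0 nodes = 1,
1–3 nodes = 2, > 3 nodes = 3) and histologic grade *G* (1–3):

```
NPI = 0.2 × S + N + G
```

with levels I (2.0 ≤ s ≤ 2.4), II (2.4 < s ≤ 3.4), III (3.4 < s ≤ 5.4) and
IV (s > 5.4). The pipeline predicts these four levels from omics alone:

1. **Align** the three gene × sample matrices and the clinical table to
   their shared complete cases.
2. **Select genes** per omic: a summed-expression chi-square ranker
   (χ²ⱼ = Σ_c (O_jc − E_jc)² / E_jc with O_jc the class-wise expression sum)
   cuts to the top *k*; mutual-information mRMR ranks for relevance minus
   redundancy; a seeded random-forest forward search over ranking prefixes
   picks the subset with the best cross-validated accuracy.
3. **Embed** the selected genes in 2-D (exact t-SNE or a self-organizing
   map) and rasterize to an injective gene → pixel **GSN template**.
4. **Render** per-sample maps: log + per-gene z-score normalization, then
   either one merged RGB image (R = expression, G = CNA, B = mRNA) or one
   single-channel map per omic ("concatenated" mode).
5. **Augment** the training set with elastic deformations (alpha 15–18) to
   balance classes.
6. **Classify** with VGG- or ResNet-style networks (7×7 kernels, swish,
   batch norm, residual blocks H(x) = F(x) + x with 1×1 mapping shortcuts),
   softmax + categorical cross-entropy, reporting accuracy and macro
   one-vs-rest AUC. The concatenated variant joins three per-omic branches
   before the head.
7. **Validate prognosis**: Kaplan–Meier relapse-free curves per NPI level.

A clinically consistent synthetic-cohort generator (`simulate_study()`)
makes the whole pipeline testable without external data: S/N/G are drawn and
labels *derived* through the NPI formula, and 10 of 500 genes carry a
level-ordered multi-omics signal. See `vignettes/gsnpi-methods.Rmd` for the
model details and every design decision.

## Worked example

```r
library(gsnpi)

cfg <- simulation_config(n_samples = 120, n_genes = 80, n_informative = 6,
                         seed = 42)
study <- simulate_study(cfg)
head(study$clinical[, c("sample_id", "tumor_size_cm", "positive_nodes",
                        "grade", "npi_score", "npi_level")], 4)
#>   sample_id tumor_size_cm positive_nodes grade npi_score npi_level
#> 1 S0001              1.65              1     2      4.33 III
#> 2 S0002              3.72              5     3      6.74 IV
#> 3 S0003              1.07              1     2      4.21 III
#> 4 S0004              1.53              7     2      5.31 III
```

Each row's score is 0.2 × size + node category + grade; S0002 has
0.2 × 3.72 + 3 + 3 = 6.74, above 5.4, hence level IV. Hybrid feature
selection on the expression layer:

```r
sel <- select_features(study$matrices$expression, study$clinical$npi_level,
                       top_k = 20, max_subset = 6, folds = 3, seed = 1)
sel
#> <forward_search_result> chosen size 6 (CV accuracy 0.933)
#> genes: G0029, G0072, G0046, G0052, G0078, G0012
```

The wrapper kept six genes whose random-forest cross-validated accuracy is
0.933. The whole pipeline, end to end on a small simulated cohort:

```r
mf <- run_pipeline(pipeline_config(
  seed = 7, out_dir = tempfile(),
  simulate = list(n_samples = 120, n_genes = 80, n_informative = 6),
  select = list(top_k = 20, max_subset = 5, folds = 3),
  embed = list(grid_size = 16), model = list(epochs = 8, batch_size = 16)))
mf
#> <run_manifest> 10 stages; val_acc 0.708, val_auc 0.991

glance(mf$model)
#>   model  preset  counted_depth epochs   acc val_acc  loss val_loss   auc val_auc
#> 1 resnet reduced             7      8 0.854   0.708 0.630    0.562 0.964   0.991
```

At this deliberately tiny scale (96 training maps of 16 × 16 px, 8 epochs)
the reduced ResNet separates the four levels far above the 0.25 chance
level; under the generator's default conditions (400 samples, 32-px maps,
20 epochs) validation accuracy approaches 1. `report(mf)` writes a markdown
summary (selected genes per omic, the performance table above, stage
timings), `autoplot()` methods draw embeddings, templates, sample maps,
training histories and survival curves, and `tidy()`/`glance()` return the
training history and final metrics as tibbles.

A thin command-line wrapper lives at `inst/cli/gsnpi.R`:

```sh
Rscript inst/cli/gsnpi.R run --seed 1 --out-dir runs/demo
```

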