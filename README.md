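# braingat

Graph-attention-network classification of multimodal brain connectomes,
with a built-in interpretability layer.

## The problem

Neurodegenerative disorders such as Parkinson's disease disturb both the
white-matter scaffold of the brain (structural connectivity, SC, from
diffusion-MRI tractography) and the temporal synchrony of regional activity
(functional connectivity, FC, from resting fMRI). Given per-subject SC and
FC matrices over the 86-region Desikan-Killiany parcellation plus regional
morphology, `braingat` answers two questions:

1. **Can patients be distinguished from controls from their connectomes?**
   Each subject is a graph: nodes are the 86 regions, the attention
   structure is the thresholded SC graph, and each node carries a
   24-feature multimodal description — 2 morphological (volume, cortical
   thickness), 7 + 4 SC network/statistical and 7 + 4 FC
   network/statistical features (clustering coefficient CC, betweenness BC,
   degree D, strength S, local efficiency LE, nodal modularity Mod,
   participation coefficient PC; mean/std/skew/kurtosis of each node's edge
   distribution). A two-layer graph attention network (GAT) computes, per
   head, attention coefficients over each node's neighborhood

       alpha_ij = softmax_j( LeakyReLU( a' [W h_i || W h_j] ) )

   and node updates `h'_i = ELU( sum_j alpha_ij W h_j )` — 6 concatenated
   heads, then a single-head output layer; a top-k readout concatenates the
   k = 20 node embeddings with the largest L2 norm into a graph embedding
   classified by fully connected layers with a 2-way softmax. Class
   imbalance is handled by SMOTE interpolation of flattened connectomes,
   with all network features recomputed on the reconstructed graphs.
   Training, 10-fold cross-validation, a stratified 10/80-20 split and a
   label-permutation significance test complete the loop.

2. **What drove the prediction?** Per-head *fidelity scores*
   (`F = mean[1(correct) - 1(correct after masking the head)]`) rank
   attention heads by their contribution; *gradient saliency* `|dy/dh|`
   (computed from the package's analytic backpropagation — no autodiff
   framework is used) maps which node/feature inputs mattered; averaged,
   symmetrized attention matrices show which region pairs the model
   attends to; and salient node features are correlated with clinical
   variables (AAO, DOI, UPDRS-III, H&Y, MMSE, LEDD) by Pearson's r at
   uncorrected p < 0.005.

Because imaging cohorts of this kind cannot be redistributed, the package
includes a synthetic-cohort generator with planted node-level effects
(default: SC weights halved on bilateral putamen/pallidum and right
thalamus in 75 patients vs. 34 controls), which makes every stage testable
and provides known recovery targets.

## Worked example

```r
library(braingat)

cfg <- synthetic_config(n_patients = 30, n_controls = 18, n_nodes = 30,
                        affected_nodes = c(2, 3, 10), sc_effect = 0.5,
                        seed = 7)
cohort <- generate_cohort(cfg)
cohort
#> <cohort_dataset> 48 subjects (30 patients, 18 controls), 30 nodes, synthetic

res <- run_pipeline(cohort, run_config(
  model = gat_config(readout_k = 8),
  train = train_config(epochs = 40, patience = 15, seed = 7),
  folds = 5, saliency_threshold = 0.005, seed = 7))

res$cv
#> 5-fold CV: accuracy 1.000 +/- 0.000, F1 1.000
res$test_metrics
#> accuracy 1.000 | precision 1.000 | recall 1.000 | F1 1.000

head(res$fidelity, 3)
#>   layer head   fidelity
#> 1     1    6 0.09090909
#> 2     1    1 0.00000000
#> 3     1    2 0.00000000

head(res$salient[, c("region", "feature", "score")], 3)
#>        region feature      score
#> 125 region_02 SC_skew 0.02808461
#> 143 region_20 SC_skew 0.02513548
#> 169 region_02   FC_CC 0.02345899

subset(res$clinical, significant)[1:2, c("node", "feature", "clinical", "r", "p")]
#>    node feature clinical          r            p
#> 31    3 SC_mean      AAO -0.7858924 2.663022e-07
#> 61    3    SC_S      AAO -0.7858924 2.663022e-07
```

Reading the output: the planted effect (SC reduction on nodes 2, 3, 10,
0-based) makes the cohort cleanly separable (CV and test accuracy 1.0 at
this effect size); head 6 of layer 1 is the only head whose masking costs
accuracy (fidelity 0.09 = 1 validation graph in 11); the top salient
entries sit on planted nodes (`region_02`, 0-based node 2, is one of
them); and the age-at-onset coupling planted in the generator is recovered
as a strong negative correlation with the SC strength and mean of node 3
(0-based node 2) at p far below 0.005.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/braingat.R simulate --out /tmp/cohort --seed 7
Rscript inst/cli/braingat.R run --manifest /tmp/cohort/manifest.csv \
    --matrices /tmp/cohort --out /tmp/run --epochs 40 --folds 5 --seed 7
```

## Package layout

- `R/connectivity.R`, `R/cohort.R`, `R/atlas.R` — data model and I/O
  (delimited matrices, manifest CSV, bundled 86-region atlas table)
- `R/features.R` — nodal network measures, edge-distribution moments,
  multimodal assembly, min-max scaling
- `R/smote.R` — SMOTE balancing on flattened connectomes
- `R/gat.R`, `R/train.R` — the attention network with analytic backprop;
  Adam training, splits, CV, metrics, permutation test
- `R/interpret.R` — fidelity, saliency, attention summaries, clinical
  correlation
- `R/synthetic.R` — cohort generator and hand-checkable micro fixtures
- `R/pipeline.R`, `inst/cli/braingat.R` — orchestration and CLI
- `vignettes/braingat-methods.Rmd` — the model, its assumptions, and every
  numerical design choice
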