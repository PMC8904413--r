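---
title: "Classifying brain connectomes with graph attention: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying brain connectomes with graph attention: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(braingat)
```

## The problem

Parkinson's disease and related neurodegenerative disorders disturb both the
white-matter scaffold of the brain (structural connectivity, SC, estimated by
diffusion-MRI tractography) and the synchrony of regional activity
(functional connectivity, FC, estimated from resting fMRI correlations).
`braingat` implements an end-to-end graph classifier for such cohorts: each
subject is a weighted graph over the 86 Desikan-Killiany regions (68
cortical, 18 subcortical), each node carries a 24-dimensional multimodal
description, and a two-layer graph attention network (GAT) attending over the
structural graph predicts patient vs. control. Because the model's attention
coefficients and input gradients are meaningful quantities, the package also
ships the corresponding interpretability layer: attention-head fidelity
scores, gradient saliency maps, averaged attention matrices, and correlation
of salient node features with clinical variables.

## Connectome preprocessing

Structural matrices hold nonnegative tractography connection probabilities;
they are thresholded absolutely at `t = 0.1` (non-strict: a value exactly at
the threshold survives), the conventional cut that removes weak, likely
spurious streamline evidence. Functional matrices hold signed Pearson
correlations; they are Fisher-z transformed (`atanh`) and then
density-thresholded, keeping the top `ceiling(0.5 * E)` of the `E = n(n-1)/2`
possible edges. Two genuinely open choices here:

* **Signed vs. absolute ranking.** After Fisher z the "strongest"
  connections could mean most positive or largest in magnitude. The default
  ranks by signed value (most positive retained), with
  `rank_by = "absolute"` available. With typical resting-state matrices at
  density 0.5 the two disagree only in the weak tail.
* **Ties and zeros.** Boundary ties are broken by (row, col) lexicographic
  order so results are machine-independent, and exactly-zero entries are
  never counted as connections — this makes density thresholding idempotent,
  which would otherwise fail when retained negative edges rank below
  removed-then-zeroed ones.

Matrices with asymmetry up to `1e-6` are averaged with their transpose;
anything larger raises an error rather than silently symmetrizing, since
genuine asymmetry at that scale indicates an upstream bug, not numerical
noise.

## The multimodal node feature set

Each node gets 24 features in a fixed, documented column order:
2 morphological (regional volume, cortical thickness) + 7 SC network +
4 SC statistical = 13 structural-side columns, then 7 FC network + 4 FC
statistical = 11 functional-side columns. The network block is the standard
weighted nodal battery: clustering coefficient (Onnela form, weights
rescaled to max 1 so CC stays in [0, 1]), betweenness centrality (shortest
paths on lengths 1/w), degree, strength, local efficiency, nodal modularity,
and participation coefficient. Three operationalizations deserve comment:

* **Nodal modularity.** "Modularity" is a global quantity; as a *node*
  feature we use node i's within-module contribution to Newman's Q,
  `Mod_i = sum_{j in module(i)} (w_ij - s_i s_j / 2W) / 2W`, chosen because
  it is the unique additive decomposition with `sum_i Mod_i = Q` — which the
  tests verify directly.
* **Local efficiency.** The weighted Brain-Connectivity-Toolbox form:
  paths between the neighbors of i restricted to the neighbor-induced
  subgraph, on cube-rooted lengths, normalized by `k_i (k_i - 1)`.
* **Statistical moments.** Mean, population SD, skewness and *excess*
  kurtosis of each node's full off-diagonal row, zeros included — the row
  after thresholding *is* the node's connection profile, and dropping zeros
  would conflate sparsity with strength. A nonzero-only mode is available
  (`include_zeros = FALSE`). Zero-variance rows get skew = kurt = 0 by
  convention.

Community structure for Mod and PC comes from Louvain on the (negative-
truncated) weights, seeded for determinism. FC negative weights are zeroed
for all network measures (their path-based definitions are undefined for
signed weights); the statistical moments keep sign. Cortical thickness is
anatomically undefined for the 18 subcortical regions and is imputed as 0 to
keep the morphology block rectangular.

Features are min-max normalized to [0, 1] per feature, with the scaler
fitted on training subjects only; held-out subjects may map outside [0, 1].
A scaler fitted on everything would leak test information into training; the
leakage-safe default is used everywhere, including inside each CV fold.

## Cohort balancing

Cohorts of this kind are imbalanced (the emulated design is 75 patients vs.
34 controls). SMOTE interpolates new minority subjects on flattened vectors
[SC upper triangle | FC upper triangle | morphology] of length 7482 for 86
nodes, each synthetic vector lying on the segment between a minority subject
and one of its `k = 5` nearest minority neighbors. Matrices are then rebuilt
from the triangles and *all graph-derived features are recomputed on the
reconstructed graphs* — interpolation does not commute with the nonlinear
network measures, so interpolating features directly would misstate them.
Balancing precedes the train/test split by default (150 samples first, then
the 10% test cut); note this lets synthetic subjects share information
across splits, so a leakage-safe variant (split first, augment the training
set only) is available by calling `augment_cohort()` after
`split_dataset()` or via `cross_validate(augment_within = ...)`. Synthetic subjects carry no clinical values; clinical
correlation uses real patients only.

## The attention network

Per head, attention scores between neighboring nodes are
`e_ij = LeakyReLU(a' [W h_i || W h_j])` (slope 0.2), softmax-normalized over
each node's neighborhood, and node embeddings update as
`h'_i = ELU(sum_j alpha_ij W h_j)`. The neighborhood is the binarized
thresholded SC graph plus a self-loop; edge weights are deliberately not
used inside attention. The hidden layer runs 6 heads of width 8 and
concatenates them (width 48); the output layer is a single head (width 8),
where concatenation vs. averaging coincide. A top-k readout ranks nodes by
the L2 norm of their final embedding (ties to the lower index) and
concatenates the top `k = 20` embeddings, giving a 160-dimensional graph
embedding classified by fully connected layers [64, 16, 2] with ReLU,
dropout 0.5, and a 2-way softmax. The norm-based ranking was chosen over a
learned scoring because it is parameter-free, deterministic, and directly
interpretable (the selected nodes are reported); selection is global per
graph rather than per feature channel.

Forward and backward passes are implemented analytically in base R matrix
algebra — no autodiff framework is involved — which is what makes the exact
gradient saliency and the finite-difference verification in the test suite
possible. Training is Adam (lr 5e-3, weight decay 5e-4 on weight matrices,
minibatch 16) with early stopping on validation loss (patience 30, best
parameters restored); all randomness (init, batching, dropout) flows from
one integer seed and reruns are byte-identical.

## Evaluation

Splits are stratified: 10% test, then 80/20 train/validation, with
largest-remainder per-class rounding (a balanced 150-subject cohort gives
exactly 108/27/15). Cross-validation is stratified k-fold (default 10) with
the scaler refit inside each fold; the reported CV accuracy is the mean of
per-fold validation accuracies. `cross_validate(augment_within = ...)`
moves SMOTE inside the folds (training subjects only), and
`train_config(class_weights = TRUE)` offers inverse-frequency weighted
cross-entropy as a balancing alternative that creates no synthetic
subjects. Metrics treat patients (label 1) as the positive class;
F1 = 2PR/(P+R), defined as 0 when P + R = 0. Significance uses a
label-permutation test with the add-one estimator
`p = (1 + #(null >= obs)) / (1 + B)`; the faithful mode retrains per
permutation, and a cheap mode (train once, permute evaluation labels) is
provided for smoke tests and calibration checks and labeled approximate.

Two properties of this evaluation design deserve explicit warning. First,
with an imbalanced cohort the chance level of plain accuracy is the
majority-class share (0.69 for 75/34), not 0.5, and balancing interventions
shift rather than remove the bias: a model cross-validated on a
SMOTE-balanced cohort can score well above chance on effect-free data
simply by recognizing interpolated subjects (they are smoother than real
ones) and their parents — the reason the leakage-safe options exist.
Second, a model trained on data with no class signal typically converges to
a constant-prediction optimum; its evaluation accuracy is then invariant
under label permutation, so permutation p-values concentrate at 1. Such
p-values remain valid (they are conservative, never anti-conservative) but
they are far from uniform, and the discreteness of accuracy over a small
evaluation set bounds how uniform they can ever be.

## Interpretability

* **Fidelity** (per head): replace that head's learned coefficients with a
  mask and measure the mean drop in per-graph correctness on the validation
  set. The default mask is *uniform over the neighborhood* rather than zero:
  it removes learned attention while preserving the scale of aggregated
  messages, so the score isolates the value of attention itself; a
  zero-mask mode exists. Fidelity lives in [-1, 1] in steps of 1/N.
* **Saliency**: the analytic gradient of the predicted-class probability
  with respect to the n x 24 input, absolute values averaged over correctly
  predicted validation graphs (a signed-mean mode exists). Probability
  rather than logit keeps scores comparable across samples. Entries above
  0.02 are reported as salient.
* **Attention maps**: mean per-head coefficient matrices over correctly
  predicted samples, symmetrized as (A + A')/2 for display, with a display
  threshold.
* **Clinical correlation**: Pearson r with two-sided p per salient
  node-feature against AAO, DOI, UPDRS-III, H&Y, MMSE and LEDD, flagged at
  uncorrected p < 0.005 by default (Holm/FDR can be applied downstream; it
  is off by default; the uncorrected threshold is the package's reporting convention).

## The synthetic generator

Real tractography/fMRI data cannot ship with the package, so
`generate_cohort()` draws cohorts with the statistical structure the
pipeline assumes: a 4-module community-structured SC template (within-module
edges U(0.10, 0.80), between-module U(0, 0.20), so absolute thresholding at
0.1 removes a realistic fraction of edges) with multiplicative log-normal
subject noise (sd 0.25); FC from a latent-factor model sharing the SC
community structure (node loadings U(0.35, 0.60) on module factors, 120
latent time points), which guarantees valid correlation matrices so Fisher z
and density thresholding behave as on real data; morphology Gaussian around
region-typical values; clinical variables drawn around published
movement-disorder cohort statistics (e.g. UPDRS-III 34.5 +/- 8.3,
AAO 51.1 +/- 9.1). The disease effect is planted on five motor-circuit nodes
(bilateral putamen and pallidum, right thalamus): patient SC edges touching
them are scaled by 1 - 0.5, FC factor loadings reduced by 0.3, morphology by
0.1, and age-at-onset is coupled negatively (slope -6 per SD) to the first
affected node's SC strength, so correlation recovery is testable.

What the generator does *not* emulate: spatial autocorrelation of real
parcellations, distance-dependent tractography biases, global signal and
motion artifacts in FC, hemispheric asymmetries, and site effects. Passing
recovery tests therefore demonstrates that the pipeline detects and
localizes effects of the planted kind at realistic cohort sizes — not that
it would achieve any particular accuracy on clinical data.

## Problem sizes and numerical choices

The test and acceptance experiments run at deliberately chosen desk scales:
recovery experiments use the full 86-node, 75/34 cohort with 5-fold CV and
30-epoch training (the planted effect is strong enough that training
converges in well under 30 epochs); oracle comparisons use exhaustive path
enumeration on graphs of up to 10 nodes and loop-based attention evaluation
on up to 8 nodes; permutation calibration uses 50 replicates of 19
permutations in cheap mode. Degenerate inputs are defined, not errors:
isolated nodes get CC = LE = PC = BC = 0, empty graphs get singleton
communities with Q = 0, constant features map to 0 under min-max scaling,
and zero-variance clinical series yield NA correlations flagged undefined.

## Known limitations

Training at 300 epochs on real-size cohorts is minutes-scale in pure R;
the package favors transparency and exact gradients over speed. The Louvain
partition is a stochastic heuristic — it is seeded and deterministic here,
but nodal Mod/PC values can shift between igraph versions. SMOTE before
splitting maximizes training data but is optimistic; use the
leakage-safe order for honest generalization estimates. The fidelity mask
semantics (uniform vs. zero) and the saliency reduction (absolute vs.
signed) are conventions; both are flag-controlled and the defaults are
stated above.
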