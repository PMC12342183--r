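---
title: "Graph contrastive clustering of single-cell RNA-seq data with scgcl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph contrastive clustering of single-cell RNA-seq data with scgcl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Clustering is the entry point of most single-cell RNA-seq analyses: cells
must be grouped into putative types before markers, compositions or
trajectories can be discussed. Count matrices are sparse, noisy and
high-dimensional, and naive distance-based clustering struggles. `scgcl`
implements an end-to-end *graph contrastive clustering* approach: a
graph-transformer encoder learns low-dimensional cell embeddings and a pair
of contrastive objectives simultaneously shapes those embeddings and
produces soft cluster assignments, while an *adaptive positive sampling*
(APS) step prunes unreliable positive pairs as training proceeds.

This vignette is the package's own account of the model, its assumptions,
the tunable parameters, and the numerical and design choices made where
more than one reasonable option existed.

# Preprocessing

The pipeline expects raw counts with cells as rows. `preprocess_counts()`
chains three steps:

1. **Quality control.** Cells expressing fewer than 5 genes and genes
   expressed in fewer than 5 cells are removed. Both filters are evaluated
   on the *input* matrix and applied jointly in one pass — the filter is not
   iterated to a fixed point, so a gene that drops below threshold only
   because failing cells were removed is kept. One pass is the documented
   contract; it keeps QC idempotent.
2. **Normalization.** Each cell is scaled to the median pre-scaling library
   size, then `log1p` is applied. "Log-transformation" alone underdetermines
   the scaling; median-library scaling is the standard scanpy-style default
   and keeps the transform parameter-free.
3. **Highly variable genes.** Genes are ranked by normalized dispersion
   (variance/mean on the log data, z-scored within 20 equal-frequency
   mean-bins so variability is judged against genes of similar abundance)
   and the top 3000 kept. Bins are forced to hold at least 20 genes — with
   tiny bins a z-score over two or three values is meaningless. Ties break
   by gene index, so selection is deterministic.

The cell graph connects each cell to its `k = 15` nearest neighbors by
cosine distance, symmetrized by union so every cell's chosen neighbors
count both ways; the diagonal is zero. Cosine distance makes the graph
invariant to residual per-cell scale. `k` is the one structural parameter
with real leverage: too small and clusters fragment, too large and distinct
types get wired together. When labels are unavailable `select_k()` probes a
candidate grid with short fits and picks the `k` minimizing the final total
loss; because the instance loss is not normalized by the number of
positives, its scale drifts with `k`, so treat the selector as a heuristic
and inspect the per-candidate losses it returns.

# Model

Two views of the expression matrix are generated by independent
Bernoulli(0.5) masking with inverted-dropout rescaling of survivors by
`1/(1 - mask_rate)`, so each view is an unbiased estimate of the input;
plain zero-masking is available via `rescale = FALSE`. Masks are redrawn
every mini-batch step; the graph is never perturbed. At evaluation time the
mask rate is treated as 0.

Both views pass through the same graph-transformer encoder (a Siamese
pair; an untied copy per view is available with `tied_encoders = FALSE`,
but weight sharing is what keeps the two "identical" encoders identical
throughout training). One layer computes multi-head scaled-dot-product
attention over each node's neighborhood *plus itself* — self-loops exist
only inside attention, guaranteeing the softmax is defined for isolated
nodes while keeping the stored adjacency zero-diagonal — followed by
residual + layer normalization, a two-layer position-wise feed-forward
block (width `2d`, ReLU), and a second residual + layer normalization.
Defaults: one layer, 4 heads, embedding width `d = 32`. The implementation
is plain R with analytic backpropagation; gradients of every parameter
tensor are verified against central finite differences in the test suite.

Two MLP heads project the embeddings: an instance head (`d -> d -> 32`,
ReLU) producing `z`, and a cluster head (`d -> d -> M`, ReLU, row-softmax)
producing soft labels `Y` on the probability simplex. The head
architectures are a package choice — two-layer perceptrons with a hidden
width equal to `d` — since only their output spaces are fixed by the
method.

# Losses

**Instance level.** For anchor cell *i* in one view, the positives are its
own augmentation in the other view plus every graph neighbor in both
views; the denominator runs over all cells of both views *including the
anchor's same-view self term* `exp(1/tau)`. Many contrastive
implementations drop that self term; it is kept here because the method's
printed form includes it, and `exclude_self = TRUE` provides the
conventional variant. No normalization by the number of positives is
applied, again following the printed form. Cosine similarities are bounded,
so the exponentials need no log-space tricks (the attention softmax, whose
scores are unbounded, does use max-subtraction).

**Cluster level.** The columns of `Y` are treated as M cluster
representations; each column's positive is the matching column of the
other view, with the denominator over all columns of both views. An
entropy regularizer discourages dumping all mass into one cluster:
`L_reg = log(M) - H` where `H` is the entropy of the normalized cluster
masses. The printed normalization spans both views' `2M` masses while the
bound is `log M`, which would let the "gap" go negative at perfect
uniformity; the package therefore computes the entropy per view over M
masses and averages the two views, so `L_reg` lies in `[0, log M]`, is 0
exactly at uniform masses and `log M` at a degenerate one-hot mass. The
literal joint-2M form stays available behind `joint_view_entropy = TRUE`.

The total is `alpha * L_ins + (1 - alpha) * (L_cls + L_reg)` with
`alpha = 0.5`, temperature `tau = 0.5`.

# Adaptive positive sampling

Expression neighbors are not always the same cell type. After a warm-up of
20% of the epochs, the package runs a mask-free forward pass, averages the
two views' soft labels, and smooths them one step over the graph with the
row-stochastic normalization of `A + I`. The bare summation form would
scale each smoothed row by its node degree, dragging the cosine
similarities of high-degree nodes together and breaking the simplex
interpretation of the rows; random-walk normalization keeps rows on the
simplex so the later argmax is meaningful (`aps_normalize = "none"` gives
the unnormalized variant). Pairs of cells whose smoothed soft labels have
cosine similarity at least `lambda = 0.9` form a soft-label adjacency, and
the instance loss thereafter uses the elementwise product of that matrix
with the KNN adjacency: an edge must be both an expression neighbor and
label-consistent to act as a positive. The filter is refreshed every epoch.

The warm-up fraction, refresh period and `lambda` are declared schedule
choices, not inferences: early soft labels are noise, so filtering on them
before the heads stabilize would lock in mistakes. `lambda` is deliberately
strict; at `lambda = -1` the filter is vacuous and the subgraph property
`A_final <= A`, monotone in `lambda`, is tested explicitly. With labels in
hand, `pair_sampling_quality()` scores the filter by PPV/NPV over the KNN
candidate pairs — the only pairs the filter adjudicates.

# Training

Adam at learning rate 0.001, 500 epochs by default, mini-batches by a
seeded random permutation cut into contiguous chunks (64 below 1000 cells,
256 to 2000, 512 to 10 000, 1024 beyond). Each batch trains on its induced
subgraph and the contrastive denominators are batch-local, which means the
loss scale varies with batch size; with `batch_size >= n` mini-batch and
full-batch training coincide exactly. Final assignments are the row-wise
argmax (lowest index on ties) of the *smoothed* soft labels from a
mask-free full-graph pass — the smoothed representation is the one defined
for cluster assignment, not the raw head output. All randomness flows from
one root seed split per purpose (initialization, batching, masking), so a
fit is reproducible bit-for-bit; the non-finite-loss guard aborts with the
offending component named.

The number of clusters, when unknown, is chosen by training a short-budget
model per candidate M and scoring hard labels with the mean silhouette on
the encoder embeddings `h` (Euclidean). `h` is the representation used for
visualization and is smoother than `z` or `g`; `select.space` lets you
score on the others. Ties prefer the smaller M.

# Interpretation

`integrated_gradients()` attributes each cell's assigned-cluster score to
genes by integrating the gradient along the straight path from a baseline
to the observed expression row (right-endpoint Riemann sum). Choices worth
stating:

- **Target**: the *pre-softmax* cluster-head score of the assigned
  cluster; post-softmax saturates and flattens gradients.
- **Baseline**: the zero vector — the natural "absent cell" on log-scale
  data; a mean-cell baseline is a flag away.
- **Path**: only the focal cell's row is interpolated; neighbors stay at
  observed values and the graph is fixed, so the attribution explains the
  score *in context*. Cells that cannot influence one another (non-adjacent
  for a one-layer encoder; distance > L in general, handled by coloring the
  L-step reachability graph) share forward passes, which makes full-data
  attribution affordable without changing any per-cell value — batched and
  one-at-a-time attributions agree to 1e-10 in the tests.
- **Completeness**: the attributions of a cell sum to the score difference
  between the observed row and the baseline row as the step count grows;
  at 200 steps the relative gap is below 1% for typical cells. The *relative*
  gap can look large for a cell whose assigned-cluster score barely moves
  between baseline and observation; that is a property of the ratio, not
  of the quadrature.

Per-cluster gene rankings average attributions over member cells.
`wilcoxon_markers()` provides the comparison lists: a one-vs-rest rank-sum
test per gene with Benjamini-Hochberg adjustment within group, filtered at
`q <= 0.01` and log fold-change `>= 1`, ranked by fold-change. It is a
stand-in for Seurat-style marker calling — same test family, not
numerically identical output — and `overlap_counts()` tabulates the
intersections that overlap heatmaps display.

# Synthetic data

`simulate_counts()` draws cluster labels uniformly, gives every gene a
negative-binomial mean (`base_mean`, times `2^lfc` on the cluster's own
disjoint marker set), multiplies by a lognormal per-cell library factor of
mean 1 and chosen CV, samples counts with dispersion `size` (variance
`mu + mu^2/size`), and applies independent Bernoulli dropout. This
splatter-like skeleton reproduces the features the method actually relies
on — overdispersed counts, depth variation, sparsity, cluster-specific
markers — and deliberately omits batch effects, trajectories, doublets and
gene-gene correlation. Passing tests on it therefore demonstrate correct
mechanics and recoverability under clean cluster structure, not
performance on any real tissue.

`default_fixture()` is the canonical test bed: 400 cells, 500 genes, 4
clusters, 25 markers per cluster at log2 fold-change 2.5, 30% dropout,
library CV 0.3, seed 7. It is separable enough that the full pipeline
recovers the planted partition (ARI above 0.99 across seeds) and small
enough to train in well under a minute on one CPU.

# Problem sizes used in the checks

The shipped tests and the acceptance script run the fixture at 150
training epochs — the loss plateaus well before that at this problem size —
with a 60-epoch probe budget per candidate during silhouette selection,
and smaller 120-150-cell simulations for unit-level checks. The package
default remains 500 epochs; nothing in the method depends on the shorter
budgets beyond convergence having occurred.

# Known limitations

- Dense attention masks make memory quadratic in the batch (and in n for
  the final full-graph pass); comfortable to a few thousand cells,
  inappropriate for atlas-scale data without a sparse attention kernel.
- The loss-based `select_k()` heuristic compares losses whose scale drifts
  with `k` (no positive-count normalization); it is a screening tool.
- The Wilcoxon marker table is not a Seurat replacement and makes no
  pseudo-bulk or latent-confounder corrections.
- Training is single-threaded CPU; the design favors exactness and
  reproducibility (bit-identical fits per seed) over speed.

# A worked run

```{r, eval = FALSE}
library(scgcl)

sim <- default_fixture()
pp <- preprocess_counts(sim$counts)
graph <- build_knn_graph(pp, k = 15)

fit <- fit_scgcl(pp, graph, n_clusters = 4,
                 opts = scgcl_config(max_epochs = 150), seed = 1)
cluster_metrics(sim$truth, fit$hard_labels)

q <- pair_sampling_quality(fit$a_final, graph, sim$truth)
ig <- integrated_gradients(fit, pp, graph, n_steps = 50)
top <- rank_attributed_genes(ig, fit$hard_labels, top_k = 200)
```
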