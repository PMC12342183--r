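# scgcl — graph contrastive clustering for single-cell RNA-seq

`scgcl` clusters single-cell RNA-seq count matrices end to end. It is
aimed at analysts who want a clustering that (i) uses the cell-cell
neighborhood structure rather than treating cells independently, (ii)
produces soft cluster assignments alongside embeddings in one training
run, and (iii) can explain each cluster in terms of genes.

## The method

Starting from a QC-filtered, log-normalized, HVG-reduced matrix
`X (n × p)`, the package builds a cosine K-nearest-neighbor graph `A` over
cells and trains a graph-transformer encoder on two randomly masked views
`X⁽¹⁾, X⁽²⁾` of the data. A multi-head attention layer aggregates each
cell's neighborhood,

    h_i ← Norm, FFN, residual ∘ ‖_k Σ_{j ∈ N_i ∪ {i}} softmax_j((Q_k h_i · K_k h_j)/√d_k) V_k h_j,

and two MLP heads project the embeddings: an instance head `z` and a
cluster head `Y` with row-softmax over the M clusters. Training minimizes

    L = α · L_ins + (1 − α) · (L_cls + L_reg),

where `L_ins` is a neighbor contrastive loss (the anchor's positives are
its other-view augmentation plus all graph neighbors in both views),
`L_cls` contrasts the M cluster columns of `Y` across views, and
`L_reg = log M − H(cluster masses)` penalizes collapsing into few
clusters. After a warm-up, an adaptive positive sampling step smooths the
soft labels over the graph, thresholds pairwise soft-label cosine at `λ`,
and replaces `A` in `L_ins` by `A_final = A ⊙ Â`, so only pairs that are
both expression neighbors and label-consistent act as positives. Final
labels are the argmax of the smoothed soft labels.

Interpretation: integrated gradients attribute each cell's assigned
pre-softmax cluster score to genes; per-cluster mean attributions give
ranked gene lists which can be compared with Wilcoxon one-vs-rest markers
via overlap counts. ARI, NMI and Hungarian-matched accuracy score results
against reference labels. A negative-binomial simulator with planted
markers and dropout makes the whole pipeline runnable without downloads.

The encoder, losses, backpropagation and the Adam loop are implemented in
plain R (BLAS-backed); every gradient is verified against finite
differences in the test suite, and fits are bit-reproducible per seed.

## Worked example

```r
library(scgcl)

sim   <- default_fixture()              # 400 cells, 500 genes, 4 clusters
pp    <- preprocess_counts(sim$counts)  # QC -> log-normalize -> HVG
graph <- build_knn_graph(pp, k = 15)

fit <- fit_scgcl(pp, graph, n_clusters = 4,
                 opts = scgcl_config(max_epochs = 150), seed = 1)
cluster_metrics(sim$truth, fit$hard_labels)
#> $ari
#> [1] 0.9939609
#> $nmi
#> [1] 0.9900293
#> $acc
#> [1] 0.9975

pair_sampling_quality(fit$a_final, graph, sim$truth)[c("ppv", "npv")]
#> $ppv
#> [1] 1
#> $npv
#> [1] 0.926045
```

The metrics say the fitted partition reproduces the planted one almost
exactly (ARI/NMI/ACC near 1), and the APS filter keeps only true same-type
neighbor pairs (PPV 1.00) while most of the pairs it discards are indeed
cross-type (NPV 0.93) — compared with PPV 0.87 for the unfiltered KNN
graph.

A command-line shell over the same functions is installed at
`inst/scripts/scgcl`:

```sh
Rscript inst/scripts/scgcl simulate   --out sim --seed 7
Rscript inst/scripts/scgcl preprocess --in sim/counts.csv --out pre --k 15
Rscript inst/scripts/scgcl fit        --in pre --m 4 --out fit --seed 1
Rscript inst/scripts/scgcl evaluate   --labels fit/labels.csv --truth sim/truth.csv --out metrics.json
Rscript inst/scripts/scgcl interpret  --fit fit --in pre --out ig --truth sim/truth.csv
```

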