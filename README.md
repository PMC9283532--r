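# spatialflow

Spatially regularized graph embeddings for spatial transcriptomics (ST)
data, in R. Given a count matrix and per-cell spatial coordinates, the
package learns a low-dimensional embedding in which cells are close when
they are similar in expression *and* spatially proximal, then derives:

* **domain segmentation** — Leiden clustering of the embedding;
* a **pseudo-spatiotemporal map (pSM)** — diffusion pseudotime from a
  deterministically chosen root cell, ordering cells coherently in space
  and pseudo-time;
* **domain marker genes** — Wilcoxon rank-sum tests with
  Benjamini–Hochberg correction.

## The model in brief

Cells become nodes of a *spatial expression graph*: node features are the
log-normalized expression of highly variable genes, edges are the
1-skeleton of the alpha complex of the coordinates at radius δ (estimated
from k-nearest-neighbour distances; a kNN graph is the alternative). A
two-layer GCN encoder ε(X, A) = H is trained with a contrastive
graph-infomax objective — a bilinear discriminator D(h, s) = σ(hᵀΘs) must
tell true embeddings from those of a feature-permuted graph, given the
graph summary s = σ(mean h) — plus a spatial regularizer

    L = L_disc + γ · mean over cell pairs of  d̂_spatial · (1 − d̂_embed),

with distances max-normalized over the evaluated pair set and γ = 0.1 by
default. The regularizer pushes apart embeddings of spatially distant
cells even when their expression is similar. Everything (forward pass,
analytic gradients, Adam, early stopping) is implemented in base R +
Matrix; gradients are pinned down by finite-difference tests.

Because real ST benchmarks need external data, the package ships a
negative-binomial synthetic-tissue generator (layered and gradient
designs, with planted marker genes and a known ordering coordinate) used
by the entire validation suite.

## Worked example

```r
library(spatialflow)

tissue <- simulate_layered_tissue(seed = 1)   # 600 cells, 3 layers, 300 genes
model  <- spatialflow(tissue, gamma = 0.1, max_epochs = 300, seed = 1)
model
#> Spatially regularized graph embedding
#>   cells: 600  latent dims: 50
#>   graph: alpha (1704 edges)  gamma: 0.1
#>   trained 300 epochs; best loss 0.04727 at epoch 300

labels <- segment_domains(model$embeddings, n_neighbors = 50,
                          target_k = 3, seed = 1)
adjusted_rand_index(labels, tissue$layer_labels)
#> [1] 0.955702

psm <- compute_psm(model$embeddings, n_neighbors = 50)
plot(model, color = "psm", psm = psm)   # spatial map of the pseudotime
```

The ARI of 0.96 against the planted layers says the segmentation recovered
the three tissue bands almost perfectly; on the gradient tissue design the
pSM correlates with the planted ordering coordinate at |Spearman ρ| ≈ 0.96.

A file-based pipeline (MTX/CSV in, CSV artifacts out) is available through
`run_pipeline()` / `sf_config()` and the thin CLI at
`inst/scripts/spatialflow` (subcommands `run`, `simulate`, `preprocess`,
`graph`, `train`, `segment`, `psm`, `markers`, `evaluate`).

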