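---
title: "Spatially regularized graph embeddings: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially regularized graph embeddings: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialflow)
```

## The problem

Spatial transcriptomics (ST) measures a count matrix (cells or capture spots
by genes) together with the physical position of every cell. Clustering the
expression alone ignores that nearby cells belong to the same tissue
structure; clustering the positions alone ignores biology. This package
learns a low-dimensional embedding $h_i \in \mathbb{R}^{N_F}$ per cell that
is consistent in *both* senses: cells end up close in latent space when their
expression is similar *and* they are spatially proximal. Domain segmentation
(Leiden clustering of the embedding) and a pseudo-spatiotemporal map (pSM,
diffusion pseudotime on the embedding) are derived downstream.

## Model

**Spatial expression graph (SEG).** Cells are nodes carrying preprocessed
expression features $x_i$; edges encode spatial adjacency. The default
adjacency is the 1-skeleton of the alpha complex at radius $\delta$: an edge
$(i,j)$ exists iff the two Voronoi cells, each intersected with the closed
ball of radius $\delta$ around its site, share a point. $\delta$ is a single
global radius, estimated as the mean over cells of the mean distance to
their $k$ (default 15) nearest neighbours. A kNN graph (union-symmetrized)
is available as an alternative and is the fallback for 3-D coordinates.

**Encoder.** A two-layer graph convolutional network with symmetric
normalization and self-loops,
$\hat A = \tilde D^{-1/2}(A + I)\tilde D^{-1/2}$, and PReLU activations:

$$H = \mathrm{PReLU}_2\!\left(\hat A\, \mathrm{PReLU}_1\!\left(\hat A X W_1\right) W_2\right).$$

Both layers have width $N_F$ (default 50).

**Contrastive objective.** Training follows the graph-infomax recipe: a
summary vector $s = \sigma(\mathrm{mean}_i\, h_i)$ is paired with true
embeddings (positives) and with embeddings of a corrupted graph whose node
features were row-permuted while the adjacency stays fixed (negatives). A
bilinear discriminator $D(h, s) = \sigma(h^\top \Theta s)$ scores pairs, and
the minimized loss is the binary cross-entropy

$$\mathcal{L}_{\mathrm{disc}} = -\tfrac{1}{2N}\Big[\sum_i \log D(h_i, s) +
\sum_j \log\big(1 - D(\tilde h_j, s)\big)\Big].$$

A fresh permutation is drawn every epoch (a single fixed corruption would
let the discriminator memorize it).

**Spatial regularization.** Over a set $P$ of ordered cell pairs, with
spatial distances $d^{(s)}$ and embedding distances $d^{(z)}$ each
normalized by its maximum over $P$,

$$\mathcal{L}_{\mathrm{reg}} = \frac{1}{|P|}\sum_{(i,j)\in P}
\hat d^{(s)}_{ij}\big(1 - \hat d^{(z)}_{ij}\big),$$

which penalizes spatially distant pairs that sit close in latent space.
The total loss is $\mathcal{L}_{\mathrm{disc}} + \gamma\,
\mathcal{L}_{\mathrm{reg}}$ with $\gamma = 0.1$ by default — a loose prior:
larger values favour spatially smooth embeddings at the cost of expression
texture. $P$ is all ordered pairs up to 10,000 cells; above that a fixed
number of pairs is resampled uniformly per step, which makes the cost per
step constant in $N$.

All forward/backward computations (including the gradient of the
max-normalized regularizer) are implemented analytically in base R and
verified against finite differences in the test suite; optimization is Adam
(learning rate $10^{-3}$) with early stopping (minimum 100 epochs, patience
50, maximum 1000) tracking the best total loss, whose parameter snapshot is
returned.

## Downstream

* **Segmentation**: Leiden community detection (modularity objective) on a
  union-symmetrized Euclidean kNN graph of the embedding, neighbourhood size
  50 for smooth domains. When a target number of domains is requested, the
  resolution is bisection-searched in $[10^{-3}, 10]$.
* **pSM**: diffusion pseudotime from the root cell (largest summed embedding
  distance to all others, ties to the lowest index). The diffusion kernel is
  Gaussian with adaptive per-cell bandwidth (distance to the
  $\lceil 50/2 \rceil$-th neighbour); pseudotime is the diffusion distance
  to the root over the 10 leading non-trivial spectral components weighted
  by $\lambda/(1-\lambda)$, shifted to 0 at the root and scaled to maximum
  1. Disconnected embedding graphs are handled per component; unreachable
  cells get value 1 with a warning.
* **Markers**: per-domain one-vs-rest Wilcoxon rank-sum tests (normal
  approximation with tie correction, as in common single-cell practice) with
  Benjamini–Hochberg correction across genes within each domain,
  significance at adjusted $p < 0.01$.

## Preprocessing

Genes detected (count > 0) in fewer than 3 cells are dropped, then cells
expressing fewer than 100 surviving genes — one pass, genes first, no
iteration to a fixed point. Counts are scaled so every cell totals 10,000
and transformed with $\log(1+x)$. Highly variable genes are chosen by
binned dispersion on the log-normalized matrix: per-gene dispersion
(variance/mean), 20 equal-frequency bins of the gene means, normalized
dispersion $|d - \mathrm{median}_{\mathrm{bin}}|/\mathrm{MAD}_{\mathrm{bin}}$
(bin standard deviation when the MAD is 0, and 0 when both vanish), top
3000 genes kept in original order, boundary ties broken by gene index.
Whether the dispersion statistics should be computed before or after the
log transform is a genuinely open choice; the package uses the
log-normalized matrix, the last matrix constructed before selection.

## Synthetic ground truth

Real ST benchmarks require external downloads and expert annotations, so
validation runs on two generated tissue designs whose truth is known:

* **Layered tissue** — cells on a jittered unit grid split into horizontal
  bands (mirroring cortical layers): 3 layers × 200 cells, 300 genes.
  Counts are negative binomial (mean–dispersion parameterization, variance
  $\mu + 0.5\mu^2$) with baseline mean 1.0; each layer owns 20 disjoint
  marker genes at fold change 5 inside the layer. These defaults give each
  cell roughly 170 detected genes, comfortably above the preprocessing
  threshold; if a draw violates it the baseline is bumped 20% with a
  warning.
* **Gradient tissue** — 600 cells on a jittered strip; 50 program genes
  whose NB means interpolate log-linearly along x between two programs
  (fold contrast 5, matching the layered design), the first half high on
  the left, the second half high on the right. The ground-truth
  pseudo-spatiotemporal coordinate is the normalized x position.

What the generator does **not** emulate: spatially autocorrelated noise,
per-spot cell-type mixtures, segmentation errors, or histology. Passing
tests therefore demonstrate correct mechanics and recoverability of planted
structure, not performance on real tissue.

Sizes used by the test suite and the acceptance script (600 cells, 300
genes, 300-epoch cap, 5 seeds per stochastic claim) were chosen so a full
validation runs in minutes on one CPU while keeping the planted-signal
recovery far from threshold.

## Numerical choices and edge cases

* **Sign convention.** The infomax objective is maximized in its usual
  statement while the spatial penalty is added to it; the only reading in
  which a single optimizer handles both is to minimize the cross-entropy
  form of the discriminator objective plus $\gamma$ times the regularizer,
  which is what the package does.
* **Alpha-complex construction.** No Delaunay library is required: for each
  candidate pair (centre distance $\le 2\delta$) the shared Voronoi face is
  a segment of the perpendicular bisector; every other site contributes one
  linear inequality in the bisector parameter, and the minimal distance to
  the sites over the feasible interval has a closed form. This is exact,
  works for collinear inputs, and connects coincident points for any
  positive radius. Fully coincident point sets fall back to kNN with a
  warning, as do 3-D coordinates (the Voronoi construction is 2-D).
  A cocircular quadruple (e.g. a perfect square) yields *both* diagonals at
  the critical radius, since the shared face degenerates to the centre
  point — the set definition, not a triangulation, is authoritative.
* **Max-normalization guards.** If all spatial (or embedding) distances in
  the evaluated pair set are 0, that normalized matrix is taken as 0.
  With $N = 2$ the loss is identically 0 (both normalized distances are 1).
* **Subsampled regularizer.** Normalizing within the sampled pair subset
  biases the estimate slightly (the subset maximum under-estimates the
  global maximum), and the bias does not vanish as more subsets are
  averaged. Consistency is therefore judged on the sampling scale of a
  single subset estimate: the mean over 200 random 1000-pair subsets must
  sit within 3 of their standard deviations of the all-pairs value.
* **Leiden and disconnected graphs.** Communities never straddle connected
  components, but modularity at resolution 1 may subdivide a sparse
  component; exact recovery of disconnected blobs is obtained at low
  resolution or with a cluster-count target.
* **Determinism.** Every stochastic step (weight initialization, per-epoch
  permutations, pair subsampling, Leiden refinement) draws from a stream
  seeded by the single run seed; identical configuration and seed reproduce
  embeddings, labels and pSM bitwise. Distance ties in kNN construction and
  rank ties at the HVG boundary are broken by index.

## Limitations

* The regularizer assumes Euclidean spatial distance is meaningful tissue-
  wide; disjoint tissues or strongly curved geometries would need an
  adapted distance.
* Training materializes dense $N \times N$ distance matrices below the
  subsampling threshold and dense eigendecompositions in the pSM; both are
  fine for the tens of thousands of cells the method targets but not for
  millions.
* The Wilcoxon marker test uses the normal approximation; exact enumeration
  appears only as a test oracle.
* Alpha-complex adjacency is 2-D; 3-D data uses kNN adjacency.
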