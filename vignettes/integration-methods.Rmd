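---
title: "Cross-modal matching by fuzzy-smoothed embedding: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal matching by fuzzy-smoothed embedding: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxfuse)
```

## The problem

Diagonal integration aligns two datasets in which *different* feature sets
are measured on *disjoint* sets of cells — for example a CODEX protein
panel on one tissue section and scRNA-seq on dissociated cells from the
same tissue. The only a-priori bridge between the modalities is a small
set of **linked features**: features measured in, or predictable from,
both sides (a protein and its coding gene, a gene's ATAC-derived activity
score and its expression). When the linked set is small and noisy — the
**weak linkage** regime typical of 30–100-marker antibody panels against
the whole transcriptome — matching cells on the linked features alone is
unreliable, even though each modality individually resolves cell states
well.

The method implemented here exploits that asymmetry: all features of each
modality define a within-modality geometry that is used to *denoise* the
weak cross-modal bridge, and an iterative loop of joint embedding,
smoothing and combinatorial matching gradually transfers information from
all features into the cross-modal correspondence.

## The pipeline

Let $Y \in \mathbb{R}^{N_1 \times p_1}$ and $Z \in \mathbb{R}^{N_2 \times
p_2}$ be the all-feature matrices and $Y^\circ, Z^\circ \in
\mathbb{R}^{\cdot \times s}$ the linked-feature matrices whose columns
correspond one-to-one. All matrices are standardized internally
(per-feature population z-score; constant features map to zero).

1. **Meta-cells (optional, default on for the richer modality).** A k-NN
   graph on the PCA-reduced all-feature matrix is clustered with Leiden;
   the resolution is tuned by bisection until the number of communities
   lands in $[N/(\sigma + 0.5),\, N/(\sigma - 0.5)]$ for a target mean
   size $\sigma$ (default 2). Member rows are averaged. Small meta-cells
   denoise sparse data and shrink the assignment problem while nearly
   preserving resolution.
2. **Fuzzy smoothing.** Each modality gets a self-inclusive k-NN graph
   $G$ (binary, row degrees $k_i$, built on all features). The smoothing
   operator is the convex combination
   $\mathcal{S}(A; w) = wA + (1-w)K^{-1}GA$, i.e. each row is shrunk
   towards its graph-neighborhood mean. $w = 1$ is the identity, $w = 0$
   pure neighborhood averaging; the default $w_0 = w_1 = 0.7$.
3. **Initial matching.** The smoothed linked matrices are rank-reduced by
   projecting every row onto the leading singular subspace of its side
   (the projection is expressed in the shared linked-feature coordinates,
   so the two sides remain directly comparable), a cross-modal distance
   matrix is computed (default $1 -$ Pearson), and a minimum-cost linear
   assignment — solved exactly by a shortest-augmenting-path algorithm —
   produces $n_{\min} = \min(n_1, n_2)$ matched pairs, the *initial
   pivots*.
4. **Iterative refinement** (default $T = 3$): fit a canonical
   correlation analysis on the current pairs' PCA-reduced all-feature
   rows; score *all* cells (pivot or not) with the CCA loadings; smooth
   the scores over the all-feature graphs with weight $w_1$; recompute
   distances and re-solve the assignment. Each iteration injects more
   all-feature information into the matching.
5. **Filtering, final embedding, propagation.** The last matching is
   ranked by distance and the closest $\lceil (1-\alpha) n_{\min} \rceil$
   pairs are kept as *refined pivots* (default $\alpha = 0$ keeps all).
   A final CCA on the pivots' all-feature rows yields loading matrices
   applied to every single cell, giving the joint embedding
   $Y^{e} = Y\hat C_1$, $Z^{e} = Z\hat C_2$ (default $r_e = 20$
   dimensions). Meta-cells not in any pivot inherit the partner of their
   nearest pivot member within their own modality (optionally thresholded
   at a percentile of those nearest-neighbor distances), in both
   directions. Meta-cell matches expand to all member-cell pairs, each
   pair is scored by the Pearson correlation of its embedding rows, and
   an optional directional pruning keeps each cell's best-scoring match.

Tri-modal integration runs two pairwise alignments that share an
intermediary modality (typically RNA), chains their refined pivots
through the shared meta-cell index, and fits a MAXVAR generalized CCA on
the chained pivots' PCA scores; the per-view loadings embed all cells of
all three modalities in one space.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `w0`, `w1` | 0.7 | smoothing weights (1 = no smoothing); unitless convex weights |
| `n_iter` | 3 | refinement iterations $T$ |
| `k_nn1`, `k_nn2` | 15 | graph neighborhood size, including self |
| `metacell_size1/2` | 2 / 1 | target mean meta-cell size; sizes of 2–3 denoise without erasing granularity, and the lower-dimensional modality is left unaggregated |
| `svd1`, `svd2` | min(30, s) | rank of the linked-feature denoising |
| `r1`, `r2` | 30 | PCA dimensions of the all-feature matrices |
| `r_cc` | 20 | CCA dimension during refinement ($\le \min(r_1, r_2)$) |
| `r_e` | 20 | final embedding dimension |
| `alpha` | 0 | pivot filtering proportion |
| `propagation_percentile` | 100 | nearest-pivot distance cut-off for propagation (percentile; scale-free) |
| `distance_metric` | correlation | cross-modal and graph metric; correlation is consistent with the Pearson match scoring, euclidean is available |
| `batch_size` | off | random-batch assignment for large inputs |

All reductions are capped at runtime to feasible ranks
(`min(p, n - 1, pairs - 1)` as appropriate), so small inputs never error
on the defaults.

## Numerical choices

- **Standardization** uses the population (divide-by-$n$) SD; constant
  features become all-zero columns rather than NaN, and zero-variance
  rows are treated as uncorrelated (distance 1) under the correlation
  metric.
- **Assignment** is solved exactly (no heuristics); ties between equal-
  cost assignments are resolved deterministically by the solver's
  augmenting order. Adding a constant to the cost matrix cannot change
  the selected pairs.
- **SVD/PCA signs** are fixed by making the largest-magnitude entry of
  each right singular vector positive, so repeated runs are identical
  across BLAS/LAPACK builds.
- **Neighbor ties** break towards the lower row index, and the self-edge
  is always present.
- **CCA regularization.** The refinement CCA operates on at most 30 PCA
  scores with many more pairs than dimensions, so it uses a barely
  perturbative ridge ($\lambda = 10^{-3}\,\mathrm{tr}(C)/p$, exactly
  classical CCA in the $\lambda \to 0$ limit, which the tests verify
  against a generalized-eigenvalue oracle). The **final** CCA is
  different: it is fit on *all* features, whose count is often comparable
  to the number of pivots. There, light ridge overfits — in-sample
  canonical correlations approach 1 on components that carry no shared
  signal, and those components pollute the embedding for every cell. The
  final fit therefore defaults to canonical-ridge shrinkage $\lambda =
  \mathrm{tr}(C)/p$ per side (`ridge_final`), which biases the loadings
  towards the cross-covariance (PLS-like) direction and generalizes far
  better off the pivot set. Both penalties are user-overridable.
- **Leiden** community detection is stochastic; every stochastic step
  (Leiden, batching) is seeded from `config$seed`, so identical inputs
  and configuration give byte-identical outputs.
- **gCCA** uses the MAXVAR formulation: leading eigenvectors of the sum
  of the views' (ridge-regularized) projection operators. With a
  duplicated view it provably reproduces two-view CCA, which the tests
  assert; this guard-rail pins down the variant.
- **Pivot filtering direction**: pairs are retained from the *smallest*
  distances up. Ranking by descending distance and keeping the top of
  that list would retain the worst matches; retaining high-quality pairs
  is the only reading consistent with the pivots' role as anchors.

## The synthetic co-assay generator

Real benchmarking of diagonal integration needs co-assayed data whose
cell-cell correspondence can be masked and then used as ground truth. The
generator emulates that design: each cell carries a latent state $L_i =
\mu_{c_i} + \varepsilon$, with cluster means placed along random
orthonormal directions scaled so that every pair of clusters is separated
at a fixed between/within variance ratio (default 8; a simplex-like
layout that guarantees separability rather than leaving it to chance).
Each modality observes $L W_m + \text{noise}$ through its own random
linear map. For each linked feature pair, the modality-2 column is
$\rho \cdot \mathrm{scale}(\text{signal}_1) + \sqrt{1 - \rho^2} \cdot
\text{independent}$, so the realized cross-modal correlation tracks the
linkage-strength knob $\rho$ directly (the independent component *is* the
noise of linked features). Rows are shuffled independently per modality
and the permutation is recorded as the masked truth. Options add
multiplicative dropout, a third modality linked through modality 2, and
removal of one cluster from one modality (mismatched populations).

What it does **not** emulate: count sampling noise (the model is
linear-Gaussian, by design, so linkage strength stays analytically
controllable), batch effects, spatial coordinates, segmentation spillover
and ATAC peak structure. Passing tests on this generator therefore
demonstrate the correctness and the information-flow claims of the
algorithm — that iterative all-feature smoothing rescues weak linkage —
not performance on any particular real assay.

Default study conditions used by the test suite and the acceptance
script: a noiseless perfectly linked pair (500 cells, 5 clusters, meta-
cells off, $T = 2$); a strong-linkage pair ($\rho = 0.9$, 2000 cells, 8
clusters, 40 linked of 800/200 features, defaults otherwise); a
weak-linkage pair ($\rho = 0.4$, 15 linked features, 1000 cells) compared
against the ablation that matches once on raw linked features
($w_0 = 1$, $T = 0$); and a clean three-modality chain (400 cells).
These sizes were chosen as the smallest instances on which the
qualitative regimes (perfect recovery, near-saturated strong linkage,
clearly separated weak-linkage gap) are stable across seeds.

## Known limitations

- The assignment step is $O(n^2)$ in memory and roughly $O(n^3)$ in the
  worst case; beyond ~$10^4$ rows per side use meta-cells and/or
  `batch_size` (random batches of the larger side are matched against the
  full smaller side, duplicates being resolved by scoring/pruning). The
  batching scheme is an approximation: it trades global optimality of the
  assignment for linear scaling in the number of batches.
- Matching quality degrades gracefully but is not guaranteed when cell
  populations are heavily mismatched between modalities; the propagation
  percentile and `alpha` are the levers to suppress forced matches.
- The final embedding is linear (CCA loadings applied to standardized
  features). Nonlinear structure shared by the modalities is captured
  only insofar as the graphs and the iterative loop surface it.
- FOSCTTM/FOSKNN require a known single-cell-level pairing and are
  therefore only available on co-assayed (or synthetic) data.

## A minimal run

```{r example, eval = FALSE}
sim <- simulate_modalities(n_cells = 1000, rho = 0.5, seed = 1)
fit <- maxfuse_fit(sim$mod1, sim$mod2, sim$linkage_12, maxfuse_config())
glance(fit)
tidy(fit)
autoplot(fit, color = "modality")
evaluate_integration(
  fit$matching, fit$embeddings[[1]], fit$embeddings[[2]],
  sim$truth$clusters[[1]], sim$truth$clusters[[2]],
  truth_pairing = sim$truth$pairing
)
```
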