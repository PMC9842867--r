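---
title: "Reconstructing 3D chromosome structure from Hi-C contact maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 3D chromosome structure from Hi-C contact maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A cis-chromosomal Hi-C map is a symmetric `N x N` matrix of contact
frequencies `CF_ij` between binned genomic loci. `hicgcn` interprets it as an
edge-weighted undirected graph — zero entries mean "not connected" — and
poses structure inference as node regression: assign coordinates
`y_i in R^3` to every locus so that the pairwise Euclidean distances of the
predicted structure reproduce target distances derived from the contacts.

Three derived inputs feed the regressor:

1. **Wish distances.** `d(i, j) = (1 / CF_ij)^gamma`, the standard inverse
   power law of distance-restraint methods. The conversion factor `gamma` is
   unknown and chromosome-dependent; empirically it falls in `[0.1, 2]`, so
   one model is trained per value of the grid `{0.1, 0.2, ..., 2.0}`
   (`gamma_grid()`), and the structure with the highest distance Spearman
   correlation (dSCC) is kept. Pairs with `CF_ij = 0` are *excluded* from the
   targets and the loss — the conversion is undefined at zero and the
   graphical view treats such pairs as disconnected — rather than being
   mapped to an arbitrarily large distance.
2. **Node embeddings.** Hi-C gives the graph no node features, so features
   are learned: a LINE-style embedding trained by edge-sampling SGD, drawing
   edges with probability proportional to their weight and `K` negative
   nodes per positive from the weighted-degree^(3/4) noise distribution. The
   default objective is second-order proximity
   (`p2(v_j | v_i) = exp(u'_j . u_i) / sum_{k in N(i)} exp(u'_k . u_i)`,
   with separate context vectors `u'`); first-order proximity is available
   via `order = 1`. Embeddings are computed on the **raw-weight** graph; the
   balanced matrix is reserved for the convolution. The raw weights carry
   the magnitude information the embedding should encode, while the balanced
   weights are the bias-corrected mixing coefficients of the aggregation.
3. **Balanced adjacency.** Knight–Ruiz balancing rescales the map to a
   doubly stochastic matrix `e_ij = x_i CF_ij x_j`, removing locus-level
   coverage bias and bounding every edge weight in `[0, 1]` for stable
   optimization. No additional max-rescaling is applied on top of the doubly
   stochastic output.

The regressor itself is one consolidate–update graph convolution followed by
a shared multilayer perceptron:

* consolidate: `C(x_i) = sum_{j in N(i)} e_ij x_j / sum_{j in N(i)} e_ij`
  with `N(i) = { j != i : e_ij > 0 }` — a weighted mean, so strongly
  interacting neighbors dominate;
* update: `x'_i = W1 x_i + W2 C(x_i)` with square `E x E` matrices and no
  bias — self-information flows through `W1`, neighborhood information
  through `W2`;
* head: ReLU, then a four-layer MLP `E -> h1 -> h2 -> h3 -> 3`, ReLU after
  each hidden layer, linear 3-unit output so coordinates are unconstrained.

All parameters are shared across nodes. That makes the parameter count
independent of `N`, which is what lets a stored checkpoint run on a map with
a different number of loci — the basis of every generalization mode.

Training minimizes the mean squared error between the structure's pairwise
distances and the wish distances over the positive-contact pairs, full batch,
with Adam. Full-batch steps are deliberate: maps at the resolutions this
package targets have at most a few thousand loci, and batching adds variance
without a memory need.

## Generalizing a stored model

To predict on a second map of the same chromosome (different resolution,
enzyme, or cell population), the new map's embeddings must live in the space
the model was trained in. Embeddings of the same chromosome are assumed
approximately equivalent up to rotation, translation and scaling, so the
target embeddings are aligned to the source embeddings by orthogonal
Procrustes: after mean-centering, the transform minimizing
`||A T - B||_F` over orthogonal `T` is `U V'` from the SVD of `A' B`, with a
closed-form optimal uniform scale. No gradient steps are involved, and the
checkpoint is never modified.

Two open choices were resolved as follows:

* **Transform orientation.** A literal left-transform `Omega A` makes
  `Omega` an `N x N` matrix, which cannot transfer between maps of different
  `N` and, when `N > E`, leaves the SVD solution non-unique. The default
  therefore aligns in the `E`-dimensional feature space (right-multiplied
  `E x E` orthogonal transform), the standard orthogonal-Procrustes reading;
  `side = "n"` provides the literal left transform for same-shape cases.
* **Centering and scaling.** Translation and scaling are explicitly part of
  the isometry assumption, so both are estimated by default
  (`scale = FALSE` disables the latter). With them, the aligned residual
  can never exceed the unaligned Frobenius distance.

Across resolutions the matrices also differ in row count: the
lower-resolution matrix is expanded by repeating each row `k` consecutive
times (`expand_embeddings`), so row `r` of the expansion and row `r` of the
high-resolution matrix describe the same genomic interval. Zero-contact bins
are retained at read time precisely so the locus counts are exact multiples.
Generalization across enzymes or cell populations reuses the identical code
path with `k = 1`.

The dSCC reported for generalized predictions uses wish distances at
`gamma = 1`: rank correlation is invariant to the monotone map
`d -> d^gamma`, so the value is the same for every positive `gamma` and
fixing 1 makes runs comparable.

## Tunable parameters

| parameter | default | notes |
|---|---|---|
| `e_dim` | 512 | embedding size; grid-searched optimum on simulated data. Tests and the acceptance script use 64 to keep runtimes small. |
| MLP hidden widths | 256/128/64 | grid-searched optimum; reduced to 32/16/8 in the test bed. |
| learning rate | 0.001 | Adam step size, grid-searched optimum. |
| convergence threshold | 1e-5 | stop when the distance MSE (squared wish-distance units) falls below it. The explored grid was {1e-2, 1e-4, 1e-5, 1e-12}; the mid-grid value is the default and fully configurable. |
| `max_epochs` | 10000 | safety cap; threshold-only stopping can loop forever on hard instances. Capped runs are flagged, not errors. |
| LINE epochs / samples | 50 epochs, `max(10 x n_edges, 10000)` samples per epoch | standard LINE-scale choices; the embedding objective is monitored per epoch. |
| negative samples | 5 | word2vec/LINE convention. |
| initial SGD rate `rho0` | 0.025 | LINE convention, linearly decayed to 1e-4 of itself. |
| KR `tol` / `max_iter` | 1e-6 / 1000 | maximum row-sum deviation; Newton first, Sinkhorn–Knopp fallback (logged in the result's `method`). |

## Numerical choices

* **Initialization.** Glorot-uniform weights, zero biases, deterministic per
  seed (a private Mersenne Twister in the compiled trainer; the R-level
  `gcnn_params()` saves and restores the global RNG state).
* **Best-model contract.** The returned parameters are the lowest-loss set
  seen during training, so the reported loss equals the minimum of the loss
  history even if late epochs wobble.
* **Ties on the gamma grid** break toward the smaller gamma.
* **Zero distances.** If two predicted points coincide, the distance
  gradient is taken as zero for that pair (a valid subgradient) instead of
  dividing by zero.
* **ReLU after the graph layer.** The update equation itself is linear; the
  network specification makes every hidden layer ReLU-followed, and the
  graph layer is hidden, so a ReLU is applied between the update and the
  MLP. It is a configuration default rather than a structural necessity.
* **Isolated nodes** (zero neighborhood weight) consolidate to the zero
  vector and are reported; embedding leaves them at their initialization and
  flags them in the metadata.
* **Degenerate metrics.** dSCC and dRMSD require at least three masked
  pairs and a non-constant distance vector; violations are errors, not NaNs.
* **Compartment sign.** The leading eigenvector of the Pearson correlation
  matrix of the balanced map is defined up to sign; lacking external
  annotation, the larger compartment is labeled "A". Zero entries go to "B"
  and constant-profile loci are dropped, both with messages.
* **Interpolation padding.** Subdividing an `N`-point structure by `k`
  yields `k(N-1)+1` points; when a target locus count is requested the final
  coordinate is repeated (or the tail truncated), with a message.

## The synthetic test bed

`make_structure()` generates ground-truth backbones (a regular helix, a
smoothed random walk, and a two-domain geometry of two compact globules),
`structure_to_map()` inverts the wish-distance law — `CF = d^(-1/gamma)` —
so that at zero noise the conversion recovers the true distances to machine
precision, `coarsen_map()` block-sums bins into lower-resolution companions,
and `split_coverage()` binomially thins counts to emulate lower-coverage
experiments with a single parameter.

Noise is multiplicative log-normal: Hi-C counts are positive and
heavy-tailed, and a one-parameter spread knob is honest about what a generic
noise model can claim. What the generator does *not* emulate: polymer
self-avoidance and population heterogeneity (every cell shares one
conformation), restriction-site and mappability biases along the genome,
distance-dependent noise structure, and trans contacts. Passing the test bed
therefore demonstrates the correctness of the machinery — conversion,
balancing, convolution, optimization, alignment, metrics — and recovery in a
well-specified regime, not performance on experimental maps.

Problem sizes in the test suite and acceptance script (30–100 loci,
embedding size 64, MLP 32/16/8, 2000-epoch cap, LINE 30 epochs) were chosen
once as the smallest scales at which all of the pipeline's qualitative
behavior is visible; larger runs only sharpen the same quantities.

## Known limitations

* Single chromosome, cis contacts only; no `.hic`/`.cool` binary parsing —
  inputs are the two text dialects.
* One graph-convolution layer: one-hop aggregation by design; deeper stacks
  and attention weighting are out of scope.
* The gamma grid is the only built-in hyperparameter search.
* Embedding alignment is linear (orthogonal + scale); strongly nonlinear
  embedding drift between datasets is beyond the model's assumption.
* dSCC against wish distances is a proxy for accuracy against the unknown
  true structure; on synthetic data the package can and does also score
  against the planted geometry, but on real data external validation
  (ChIA-PET-style looped-pair comparisons via `region_distance_compare`,
  compartment consistency via `call_compartments`) is the available check.
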