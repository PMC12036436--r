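---
title: "Least-action trajectory models of cellular development: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Least-action trajectory models of cellular development: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajaction)
```

## The model

Development is treated as a stochastic process over cell states. A cell at
time step $t$ is described by its generalized coordinate
$C_t = (x_t, \dot x_t)$ — expression and RNA velocity — and a realization
of the process is a trajectory $\gamma = (C_0, \dots, C_T)$. Instead of a
Markov chain over single steps, the package models the distribution of
whole trajectories with an autoregressive sequence model
$p_\theta(\gamma) = \prod_t p_\theta(C_t \mid C_{<t})$, and scores each
trajectory with an **action**

$$\mathcal{A}_\theta(\gamma) \;=\; -\log p_\theta(\gamma)\,,$$

the surprise of the path. High-probability ("geodesic") trajectories have
low action; the mean action over an ensemble is the cross-entropy loss, so
*fitting the model is minimizing the expected action*, and the fitted model
doubles as a measurement instrument: every metric below is a functional of
$p_\theta$.

Because scRNA-seq destroys cells, trajectories are not observed directly.
They are reconstructed in four stages, each behind its own function:

1. **Configurations** (`buildConfigurations`): expression is standardized
   gene-wise and projected on its top principal axes; velocity is scaled by
   the same per-gene standard deviations (it transforms as the derivative
   of standardized expression), projected on the *same* basis, weighted,
   and concatenated.
2. **Transition kernels** (`markovTransitionProbs`,
   `memoryTransitionProbs`): for each cell $j$ of layer $t$, candidates
   $\mathcal{N}_j$ are its $k$ nearest layer-$(t{+}1)$ cells in
   configuration space, and
   $p_{j,k} = \exp(\mathrm{corr}(C_j, C_k)) / \sum_{l\in\mathcal{N}_j}
   \exp(\mathrm{corr}(C_j, C_l))$. The memory-weighted variant replaces the
   single correlation with $\sum_{m=0}^{L-1}\lambda^m\,
   \mathrm{corr}(C_{t-1-m}, C_k)$, so recent states dominate and
   $\lambda = 0$ (or $L = 1$) recovers the Markov kernel exactly.
3. **Tokenization** (`fitVocabulary`): per time layer, a Voronoi partition
   of configuration space fitted by seeded Lloyd iterations turns cells
   into a discrete vocabulary; trajectories become token sequences.
4. **Sequence models** (`fitTabular`, `trainTransformer`): an exact
   empirical back-off model serves as the chain-rule oracle; a small
   decoder-only transformer (token + cell-type + position embeddings summed
   at the input, causal self-attention, trained with Adam on the mean
   action) provides the learned $p_\theta$. `generateTrajectories` samples
   new trajectories through a nucleus filter (temperature, then top-k,
   then top-p, then renormalization).

## The three metrics

**Stepwise normalized entropy** (`normalizedEntropy`, `entropyProfile`).
At each step the next-token distribution, restricted to the layer's tokens
and temperature-scaled, has entropy $H_t$; dividing by $\log N_t$, with
$N_t$ the number of cells at that step, makes values comparable across
layers of different size. High values mean broad exploration of state
space, low values exploitation of few continuations; a valley marks a
developmental bottleneck.

**Balanced Forman curvature** (`buildMultipartiteGraph`, `edgeCurvature`,
`curvatureReport`). Trajectories induce a multipartite graph: nodes are
(token, layer) states, edges join states consecutive in some trajectory.
For an edge $i\sim j$,

$$\mathrm{Ric}(i,j) = \frac{2}{d_i} + \frac{2}{d_j} - 2
  + 2\frac{T_{ij}}{\max(d_i,d_j)} + \frac{T_{ij}}{\min(d_i,d_j)}
  + \frac{S_i + S_j}{\gamma_{\max}\max(d_i,d_j)}$$

with $T_{ij}$ the triangle count, $S_i$ the neighbors of $i$ on
diagonal-free 4-cycles through the edge, and $\gamma_{\max}$ the maximal
number of such cycles through one common node. Negative edges are bridges
(bottlenecks that oversquash information); positive edges are hubs
(redundant, robust connections). Node curvature averages incident edges.
Because the trajectory graph is bipartite between consecutive layers,
$T_{ij} = 0$ there identically and curvature is carried entirely by
degrees and 4-cycles.

**Local entropy production** (`entropyProduction`,
`localEntropyProduction`, `epMap`). Time-reversal asymmetry is measured by
$\sigma(\gamma) = k_B[\log p_\theta(\gamma) - \log p_\theta(\tilde\gamma)]$
with $k_B = 1$ (all quantities in nats), and its local version scores a
trajectory against the reversal of only the segment $[i, j]$. Under
detailed balance $\sigma \equiv 0$; the ensemble expectation equals the KL
divergence between the forward and backward trajectory distributions and is
therefore non-negative. `epMap` tabulates mean and variance of
$\sigma_{i,j}$ over an ensemble by start index and segment length.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `nPcs` | 30 | principal axes kept; configuration dimension is `nPcs` (or `2*nPcs` with velocity) |
| `velocityWeight` | 1 | weight of the velocity block; 0 = expression-only configurations |
| `knnK` | 30 | candidate-set size of the layer-to-layer KNN search |
| `memoryLambda`, `memoryWindow` | 0, 1 | exponential memory decay in [0,1] and window $L$; (0, 1) is the Markov kernel |
| `vocabSize` | 50 per layer | Voronoi centroids per time layer |
| `topK`, `topP`, `temperature` | Inf, 1, 1 | nucleus sampler; defaults are the identity filter |
| transformer | 2 blocks, width 64, 4 heads | deliberately desk-scale; all configurable via `modelConfig()` |

All stage seeds derive from one master seed through named substreams
(`stageSeed`), so identical configurations reproduce byte-identical
outputs and individual stages can be re-run in isolation.

## The synthetic generator: what it emulates, what it does not

`simulateBranchingProcess` produces layered branching populations: latent
lineage means follow a Gaussian random walk per gene (`driftScale`),
daughters copy the parent mean at a branch point and then drift apart,
cells are lineage means plus Gaussian noise, and velocity is the expected
displacement to the next-layer lineage mean plus noise — so velocity is
informative about the true direction by construction. A bottleneck
collapses the latent means of non-surviving lineages onto their common
average at one layer, shrinking state diversity there the way a
reprogramming bottleneck shrinks the accessible expression space.

It does **not** model transcription or splicing kinetics, sequencing depth,
dropout, or non-Gaussian noise; cell counts per layer are constant, and
lineage labels double as cell types. Passing tests on these fixtures
demonstrates that the estimators recover designed structure under their
own assumptions — not that real data satisfy those assumptions.

## Numerical choices and edge conventions

- `corr` is the Pearson correlation of full configuration vectors; a
  constant vector yields `corr = 0` with a warning rather than NaN.
- Zero-variance genes are dropped (with a warning) before standardization.
- KNN ties at the k-th distance and nearest-centroid ties break by
  ascending index, making candidate sets and quantization deterministic.
- $\lambda^0 = 1$ including at $\lambda = 0$, so the memory kernel reduces
  to the Markov kernel exactly, not just in the limit.
- Voronoi fitting uses Lloyd iterations with best-of-5 seeded restarts;
  empty centroids are dropped rather than reseeded.
- $0\log 0 = 0$ throughout; a single-cell layer has normalized entropy 0 by
  convention; $N_t$ in the entropy normalization is the number of *cells*
  at the step (the quantity that varies across real time points), while the
  distribution itself lives on the layer's tokens.
- Curvature: $\mathrm{Ric} = 0$ when $\min(d_i, d_j) = 1$, and the 4-cycle
  term is 0 when $\gamma_{\max} = 0$. The diagonal-free 4-cycle and
  $\gamma_{\max}$ definitions follow the balanced-Forman literature; a
  brute-force cycle enumerator in the test suite is the arbiter and agrees
  exactly on hundreds of random graphs. Multiplicities (trajectory
  traversal counts) enter only through the optional multiplicity degree
  mode; the combinatorics use the simple graph.
- Reversed token sequences place tokens in "wrong" layers; models score
  any token sequence (embeddings are position-independent inputs), which is
  what makes local entropy production evaluable. Zero-probability reversals
  give $\pm\infty$, are flagged, and are excluded from map means with their
  counts reported rather than imputed.
- The transformer uses pre-norm blocks, ReLU MLPs, and a learned
  begin-of-sequence token whose successor distribution is the empty-prefix
  distribution. Backpropagation is hand-written and checked against central
  finite differences in the tests.

## Design decisions on genuinely open points

- **Which correlation?** Whether the transition correlation uses
  expression only or the full $(x, \dot x)$ pair is not settled;
  `velocityWeight` exposes the choice (1 by default, 0 for
  expression-only) instead of hard-coding either.
- **Candidate scope.** Candidates are restricted to the next time layer;
  the multipartite trajectory graph only has consecutive-layer edges, so
  cross-layer KNN would create transitions the downstream graph could not
  represent.
- **Per-layer quantization.** Tokens are fitted per layer, so a token
  identifies both a region of state space and a time step, which makes
  layer-order accuracy of generated sequences well defined.
- **Two accuracy rates.** "Correct order" can mean the predicted token is
  in the right layer or is exactly the true next token; both rates are
  reported (`sequenceAccuracy`).
- **Entropy-valley detection.** The bottleneck test uses the profile's
  *empirical* (frequency) mode at temperature 1.0. The reason is
  structural: under a softmax-over-correlation kernel the conditional
  next-token distributions do not concentrate when states collapse (the
  collapsed cluster still spreads its mass over its own tokens), whereas
  the per-step state-frequency entropy must dip — a layer with two states
  is capped at $\ln 2 \approx 0.69$ nats while layers with four or more
  well-separated states stay above $0.9$ nats for any correlation values
  in $[-1, 1]$. At very low temperature the tempered frequencies amplify
  sampling skew and comparisons degenerate into orderings of near-zero
  numbers, so the assertion is made at $T = 1$; profiles at other
  temperatures are still computed and reported.
- **EP-map trend.** On a drift chain whose non-forward transitions share
  one probability, $\sigma_{i,j}$ is (number of forward transitions
  disturbed) times one log-ratio. Extending a segment inside the
  trajectory disturbs one more transition; extending it to the trajectory
  end disturbs none. The monotonicity tests assert exactly that structure:
  strict growth for interior extensions, flatness (within half an
  increment) for the terminal one.
- **Start distribution.** Trajectories start uniformly over layer-0 cells
  (maximum-entropy default in the absence of prior weights).
- **Arbitrary time labels** are rank-mapped to the contiguous steps
  $0..T$ with the mapping stored in the table metadata; numeric labels must
  already be contiguous so a missing time point is an error, not a silent
  re-indexing.

## Problem sizes

The suite and examples run branching lineages of 5-6 layers with 40-60
cells per layer and 30-40 genes, vocabularies of 2-12 tokens per layer,
ensembles of 150-400 trajectories, and transformers of width 16-32 trained
for up to 60 epochs — sizes chosen so every oracle (exhaustive sequence
enumeration, brute-force cycle counting, finite-difference gradients) is
exact and the whole analysis reruns in minutes on one core. All components
scale to larger instances at the usual polynomial costs (KNN and PCA in
the cell count, enumeration oracles excepted).

## Known limitations

- The transformer is a from-scratch R implementation intended for small
  vocabularies and short sequences; there is no GPU path, no batched
  attention across sequences, and no large-scale pretraining.
- Tokens decode to centroids only; there is no gene-level generative
  decoding.
- The kernel's correlation-softmax is one literal reading of
  neighbor-weighting practice; optimal-transport or pseudotime couplings
  are out of scope.
- Entropy production is reported in nats ($k_B = 1$) and is not calibrated
  to physical heat dissipation.

## A compact end-to-end example

```{r example, eval = FALSE}
spec <- lineageSpec(nLayers = 6, cellsPerLayer = 48, nGenes = 40,
  branchPoints = list(list(layer = 1, nBranches = 4, probs = rep(0.25, 4))),
  bottleneck = list(layer = 3, survivingFraction = 0.25),
  noiseSd = 0, driftScale = 1)
sim   <- simulateBranchingProcess(spec, seed = 11)
cfg   <- buildConfigurations(sim$table, nPcs = 10, velocityWeight = 0)
kern  <- markovTransitionProbs(cfg, k = 48)
ens   <- sampleTrajectories(kern, 300, seed = 12, configs = cfg)
vocab <- fitVocabulary(cfg, sim$table, 12, seed = 13)
tok   <- encodeTrajectories(ens, vocab)

entropyProfile(NULL, vocab, temperatures = 1, mode = "empirical",
               ensemble = tok)            # valley at the bottleneck layer
g <- buildMultipartiteGraph(tok, vocab)
head(curvatureReport(g)$edges)            # bridges vs hubs per edge
tab <- fitTabular(tok, maxOrder = 2, vocabSize = nTokens(vocab))
head(epMap(tab, tok))                     # local irreversibility map
```
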