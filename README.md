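# trajaction

Least-action trajectory modeling and information metrics for cellular
development.

## The problem

Time-resolved single-cell RNA-seq gives snapshots of a developing
population, never the path of any one cell: sequencing destroys the cell.
Yet the questions practitioners ask are path questions — where does the
process narrow into a bottleneck, which transitions are fragile bridges
versus robust hubs, how irreversible is a commitment step. **trajaction**
answers them by (i) reconstructing an ensemble of plausible trajectories
through expression/velocity configuration space, (ii) fitting an
autoregressive sequence model to that ensemble, and (iii) reading three
interpretable metrics off the fitted model. It is aimed at computational
biologists working with layered (time-stamped) scRNA-seq matrices plus RNA
velocity, and at methods developers who want a fully testable desk-scale
implementation with exact oracles.

## The model in brief

A cell state is the generalized coordinate $C_t = (x_t, \dot x_t)$; a
trajectory is $\gamma = (C_0,\dots,C_T)$. An autoregressive model gives
$p_\theta(\gamma) = \prod_t p_\theta(C_t \mid C_{<t})$ and every
trajectory is scored by its **action**
$\mathcal{A}_\theta(\gamma) = -\log p_\theta(\gamma)$ (nats): probable,
"geodesic" paths have low action, and the training loss is exactly the
mean action. On top of $p_\theta$:

- **Normalized stepwise entropy** $H_t / \log N_t$ — the
  exploration/exploitation balance per time step; valleys mark
  bottlenecks.
- **Balanced Forman curvature** of the multipartite trajectory graph,
  $\mathrm{Ric}(i,j) = \tfrac{2}{d_i} + \tfrac{2}{d_j} - 2
  + 2\tfrac{T_{ij}}{\max(d_i,d_j)} + \tfrac{T_{ij}}{\min(d_i,d_j)}
  + \tfrac{S_i+S_j}{\gamma_{\max}\max(d_i,d_j)}$ — negative edges are
  information bridges (oversquashing), positive edges are robust hubs.
- **Local entropy production**
  $\sigma_{i,j}(\gamma) = k_B[\log p_\theta(\gamma) -
  \log p_\theta(\tilde\gamma[i,j])]$ — time-reversal asymmetry of the
  segment $[i,j]$; zero under detailed balance, and its ensemble
  expectation equals the forward/backward KL divergence.

Trajectories are built from per-time-step transition kernels (softmax over
Pearson correlations of KNN candidates, optionally memory-weighted with
decay $\lambda$ over a window $L$), discretized by per-layer Voronoi
quantization, modeled by an exact tabular oracle and a small causal
transformer, and sampled with nucleus sampling (temperature / top-k /
top-p). A bundled generator of branching lineages with known ground truth
makes every stage testable without external data.

## Worked example

Simulate a noise-free lineage that branches four ways at layer 1 and is
squeezed through a designed bottleneck at layer 3, then measure it:

```r
library(trajaction)

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
vocab
#> Vocabulary: 19 tokens over 6 layers
#>   tokens per layer: 1 4 4 2 4 4
```

The tokens-per-layer line already shows the bottleneck: layer 3 has only 2
reachable states. The entropy profile localizes it quantitatively:

```r
entropyProfile(NULL, vocab, temperatures = 1, mode = "empirical",
               ensemble = tok)
#>   step temperature     H  N H_normalized   n
#> 1    0           1 0.000 48        0.000 300
#> 2    1           1 1.367 48        0.353 300
#> 3    2           1 1.334 48        0.345 300
#> 4    3           1 0.649 48        0.168 300
#> 5    4           1 1.269 48        0.328 300
#> 6    5           1 1.154 48        0.298 300
```

Interior steps hold ~0.33-0.35 normalized entropy except step 3, which
drops to 0.168 — the designed bottleneck layer. The same ensemble yields
the trajectory graph and its curvature; the squeezed layers are the most
negatively curved (bridge-like):

```r
tab <- fitTabular(tok, maxOrder = 2, vocabSize = nTokens(vocab))
ensembleEntropy(tab, tok)          # mean action, nats per trajectory
#> [1] 5.214645
rep <- curvatureReport(buildMultipartiteGraph(tok, vocab), "simple", vocab)
aggregate(ric ~ layer, rep$edges, mean)
#>   layer    ric
#> 1     0 -0.750
#> 2     1 -0.967
#> 3     2 -1.202
#> 4     3 -1.190
#> 5     4 -0.843
```

Irreversibility on an analytically known forward-biased chain (an exact
first-order model via `markovChainModel`): reversing longer segments
produces more entropy, and the ensemble expectation matches the
forward/backward KL divergence computed by an independent path:

```r
V <- 6; trans <- matrix(0, V, V)
for (s in 1:V) { fw <- min(s + 1, V)
  trans[s, fw] <- 0.85
  trans[s, -fw] <- 0.15 / (V - 1) }
init <- rep(0.15 / 5, V); init[1] <- 0.85
chain <- markovChainModel(init, trans, 6)
gamma <- 1:6
entropyProduction(chain, gamma)            # full reversal
#> [1] 20.06421
localEntropyProduction(chain, gamma, 2, 4) # one interior segment
#> [1] 13.37614
c(expectedEntropyProduction(chain), klForwardBackward(chain))
#> [1] 14.47851 14.47851
```

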