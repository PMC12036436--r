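## Shared fixtures, built in code at test time.

## Small branching lineage with moderate noise (general-purpose pipeline
## fixture): 5 layers x 40 cells x 30 genes, one 2-way branch at layer 2.
fixtureBranching <- function(noiseSd = 0.2, seed = 7) {
  spec <- lineageSpec(nLayers = 5, cellsPerLayer = 40, nGenes = 30,
    branchPoints = list(list(layer = 2, nBranches = 2, probs = c(0.5, 0.5))),
    noiseSd = noiseSd, driftScale = 1)
  simulateBranchingProcess(spec, seed = seed)
}

## Full pipeline over the branching fixture up to a tokenized ensemble.
fixturePipeline <- function(noiseSd = 0.2, seed = 7, nPcs = 10,
                            velocityWeight = 1, k = 10, nTraj = 60,
                            vocabPerLayer = 8) {
  sim <- fixtureBranching(noiseSd, seed)
  cfg <- buildConfigurations(sim$table, nPcs = nPcs,
                             velocityWeight = velocityWeight)
  kern <- markovTransitionProbs(cfg, k = k)
  ens <- sampleTrajectories(kern, nTraj, seed = seed + 1, configs = cfg)
  vocab <- fitVocabulary(cfg, sim$table, vocabPerLayer, seed = seed + 2)
  tok <- encodeTrajectories(ens, vocab)
  list(sim = sim, cfg = cfg, kern = kern, ens = ens, vocab = vocab, tok = tok)
}

## Noise-free lineage whose trajectory distribution is fully enumerable:
## one 2-way branch at layer 2, candidate sets spanning the full next layer
## so the branch step carries real entropy. Tokens = distinct states.
fixtureOracleProcess <- function(seed = 31, nTraj = 300) {
  spec <- lineageSpec(nLayers = 6, cellsPerLayer = 40, nGenes = 30,
    branchPoints = list(list(layer = 2, nBranches = 2, probs = c(0.5, 0.5))),
    noiseSd = 0, driftScale = 1)
  sim <- simulateBranchingProcess(spec, seed = seed)
  cfg <- buildConfigurations(sim$table, nPcs = 5, velocityWeight = 1)
  kern <- markovTransitionProbs(cfg, k = 40)
  ens <- sampleTrajectories(kern, nTraj, seed = seed + 1, configs = cfg)
  vocab <- fitVocabulary(cfg, sim$table, 4, seed = seed + 2)
  tok <- encodeTrajectories(ens, vocab)
  nTrain <- round(2 / 3 * nTraj)
  list(sim = sim, cfg = cfg, kern = kern, vocab = vocab, tok = tok,
       train = trajectoryEnsemble(as.matrix(tok)[seq_len(nTrain), , drop = FALSE],
                                  kind = "token"),
       eval = trajectoryEnsemble(as.matrix(tok)[-seq_len(nTrain), , drop = FALSE],
                                 kind = "token"))
}

## Noise-free lineage with a designed bottleneck: 4-way branch at layer 1,
## latent means of 3 of the 4 lineages collapsed at layer 3. The layer-3
## state count drops to 2 while every other interior layer keeps 4.
fixtureBottleneck <- function(seed = 11, nTraj = 300) {
  spec <- lineageSpec(nLayers = 6, cellsPerLayer = 48, nGenes = 40,
    branchPoints = list(list(layer = 1, nBranches = 4, probs = rep(0.25, 4))),
    bottleneck = list(layer = 3, survivingFraction = 0.25),
    noiseSd = 0, driftScale = 1)
  sim <- simulateBranchingProcess(spec, seed = seed)
  cfg <- buildConfigurations(sim$table, nPcs = 10, velocityWeight = 0)
  kern <- markovTransitionProbs(cfg, k = 48)
  ens <- sampleTrajectories(kern, nTraj, seed = seed + 1, configs = cfg)
  vocab <- fitVocabulary(cfg, sim$table, 12, seed = seed + 2)
  list(sim = sim, vocab = vocab, tok = encodeTrajectories(ens, vocab))
}

## Deterministic token ensemble whose multipartite graph has two dense
## complete-bipartite blocks between layers 1 and 2 joined by a single
## bridge edge (u1, y1). Layers: root(1) | u1..u3 = 2:4, x1..x3 = 5:7 |
## v1..v3 = 8:10, y1..y3 = 11:13 | sink(14).
fixtureBridgeEnsemble <- function() {
  rows <- list()
  for (u in 2:4) for (v in 8:10) rows[[length(rows) + 1L]] <- c(1L, u, v, 14L)
  for (x in 5:7) for (y in 11:13) rows[[length(rows) + 1L]] <- c(1L, x, y, 14L)
  rows[[length(rows) + 1L]] <- c(1L, 2L, 11L, 14L)   # the bridge u1 - y1
  trajectoryEnsemble(do.call(rbind, rows), kind = "token")
}

## Strictly positive forward-biased chain: one drift step right with high
## probability, the remaining mass spread evenly over every other state.
## Any non-forward transition then carries the same log-penalty, so the
## entropy production of a reversal scales with the number of forward
## transitions it disturbs, and every local reversal is scoreable.
fixtureBiasedChain <- function(nStates = 12, len = 7, drift = 0.85) {
  V <- nStates
  off <- (1 - drift) / (V - 1)
  trans <- matrix(off, V, V)
  for (s in seq_len(V)) {
    fw <- if (s < V) s + 1L else s
    trans[s, ] <- off
    trans[s, fw] <- drift + if (fw == s) off else 0
    trans[s, -fw] <- (1 - trans[s, fw]) / (V - 1)
  }
  init <- rep((1 - drift) / (V - 1), V)
  init[1L] <- drift
  markovChainModel(init, trans, len)
}

## Random strictly positive first-order chain (for property sweeps).
randomChainModel <- function(V = 3, len = 4) {
  init <- as.numeric(stats::runif(V)) + 0.05
  init <- init / sum(init)
  trans <- matrix(stats::runif(V * V) + 0.05, V, V)
  trans <- trans / rowSums(trans)
  markovChainModel(init, trans, len)
}
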