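## A tiny hand-built corpus: token a=1 (step 1) is followed by b=2 three
## times and c=3 once.
abcEnsemble <- function() {
  trajectoryEnsemble(rbind(c(1L, 2L), c(1L, 2L), c(1L, 2L), c(1L, 3L)),
                     kind = "token")
}

test_that("tabular conditionals are exact count ratios with suffix backoff", {
  tab <- fitTabular(abcEnsemble(), maxOrder = 2)
  expect_equal(nextDistribution(tab, 1L), c(0, 0.75, 0.25))
  expect_equal(sum(nextDistribution(tab, integer(0))), 1)
  ## order-2 context never seen backs off to the seen order-1 suffix
  expect_equal(nextDistribution(tab, c(3L, 1L)), nextDistribution(tab, 1L))
  ## ...and an entirely unseen suffix falls back to the position marginal
  expect_equal(nextDistribution(tab, 2L), tab@marginals[[2L]])
  ## all returned distributions are normalized
  for (pre in list(integer(0), 1L, 2L, c(1L, 2L)))
    expect_equal(sum(nextDistribution(tab, pre)), 1, tolerance = 1e-12)
})

test_that("trajectory log-probability is the chain-rule sum", {
  half <- markovChainModel(c(0.5, 0.5), matrix(0.5, 2, 2), 2)
  expect_equal(trajectoryLogProb(half, c(1L, 2L)), log(0.25), tolerance = 1e-12)
  determ <- markovChainModel(c(1, 0), rbind(c(0, 1), c(1, 0)), 3)
  expect_equal(trajectoryLogProb(determ, c(1L, 2L, 1L)), 0)
  expect_identical(trajectoryLogProb(determ, c(2L, 1L, 2L)), -Inf)
  ## per-step decomposition matches the total within 1e-12
  set.seed(1)
  m <- randomChainModel(V = 3, len = 5)
  traj <- c(2L, 1L, 3L, 3L, 2L)
  dists <- stepDistributions(m, traj)
  expect_equal(sum(log(dists[cbind(1:5, traj)])),
               trajectoryLogProb(m, traj), tolerance = 1e-12)
})

test_that("the action is the negative log-likelihood and non-negative", {
  half <- markovChainModel(c(0.5, 0.5), matrix(0.5, 2, 2), 2)
  expect_equal(trajectoryAction(half, c(1L, 2L)), -log(0.25), tolerance = 1e-12)
  set.seed(2)
  m <- randomChainModel(V = 4, len = 6)
  for (i in 1:100) {
    traj <- sample.int(4, 6, replace = TRUE)
    a <- trajectoryAction(m, traj)
    expect_gte(a, 0)
    expect_equal(a, -trajectoryLogProb(m, traj))
  }
})

test_that("ensemble entropy is the mean action and minimal for the truth", {
  ens <- abcEnsemble()
  tab <- fitTabular(ens, maxOrder = 1)
  acts <- vapply(seq_len(nTrajectories(ens)), function(i)
    trajectoryAction(tab, as.matrix(ens)[i, ]), numeric(1))
  expect_equal(ensembleEntropy(tab, ens), mean(acts), tolerance = 1e-12)
  ## N identical trajectories with model probability p give exactly -log p
  one <- trajectoryEnsemble(matrix(c(1L, 2L), 5, 2, byrow = TRUE), kind = "token")
  uni <- uniformModel(3, 2)
  expect_equal(ensembleEntropy(uni, one), -log(1 / 9), tolerance = 1e-12)
  ## Gibbs: perturbing the fitted conditionals never lowers the loss
  set.seed(3)
  pipe <- fixturePipeline(nTraj = 40)
  fit <- fitTabular(pipe$tok, maxOrder = 1, vocabSize = nTokens(pipe$vocab))
  base <- ensembleEntropy(fit, pipe$tok)
  for (rep in 1:5) {
    pert <- fit
    pert@contexts <- lapply(fit@contexts, function(p) {
      q <- p + stats::runif(length(p), 0, 0.05)
      q / sum(q)
    })
    expect_gte(ensembleEntropy(pert, pipe$tok), base - 1e-12)
  }
})

test_that("exhaustive trajectory entropy matches its closed forms", {
  expect_equal(modelTrajectoryEntropy(uniformModel(4, 3), 3)$entropy,
               3 * log(4), tolerance = 1e-9)
  determ <- markovChainModel(c(1, 0), rbind(c(0, 1), c(1, 0)), 3)
  expect_equal(modelTrajectoryEntropy(determ, 3)$entropy, 0)
  set.seed(4)
  m <- randomChainModel(V = 3, len = 4)
  res <- modelTrajectoryEntropy(m, 4)
  expect_equal(res$entropy, res$expectedAction, tolerance = 1e-9)
  expect_error(modelTrajectoryEntropy(uniformModel(50, 5), 5), "guard")
})

test_that("accuracy reports exact and layer-order rates with sane bounds", {
  pipe <- fixturePipeline(nTraj = 20)
  tab <- fitTabular(pipe$tok, maxOrder = 2, vocabSize = nTokens(pipe$vocab))
  acc <- sequenceAccuracy(tab, pipe$tok, pipe$vocab)
  expect_true(acc$exact >= 0 && acc$exact <= 1)
  expect_gte(acc$layerOrder, acc$exact)
  ## a model that always predicts the true next token scores 1.0 on both;
  ## a deterministic noise-free process realizes that model exactly
  spec <- lineageSpec(nLayers = 4, cellsPerLayer = 20, nGenes = 10,
                      noiseSd = 0, driftScale = 1)
  sim <- simulateBranchingProcess(spec, seed = 2)
  cfg <- buildConfigurations(sim$table, nPcs = 3, velocityWeight = 0)
  kern <- markovTransitionProbs(cfg, k = 5)
  vocab <- fitVocabulary(cfg, sim$table, 4, seed = 1)
  tok <- encodeTrajectories(sampleTrajectories(kern, 30, seed = 1), vocab)
  dtab <- fitTabular(tok, maxOrder = 1, vocabSize = nTokens(vocab))
  dacc <- sequenceAccuracy(dtab, tok, vocab)
  expect_equal(dacc$exact, 1.0)
  expect_equal(dacc$layerOrder, 1.0)
})

test_that("coverage is a set ratio, monotone under appending", {
  ev <- trajectoryEnsemble(rbind(c(1L, 2L), c(1L, 3L)), kind = "token")
  expect_equal(tokenCoverage(trajectoryEnsemble(rbind(c(1L, 2L), c(3L, 3L)),
                                                kind = "token"), ev), 1.0)
  expect_equal(tokenCoverage(trajectoryEnsemble(rbind(c(4L, 5L)),
                                                kind = "token"), ev), 0.0)
  gen <- matrix(c(1L, 1L), 1, 2)
  covs <- c()
  for (row in list(c(2L, 2L), c(4L, 4L), c(3L, 3L))) {
    gen <- rbind(gen, row)
    covs <- c(covs, tokenCoverage(trajectoryEnsemble(gen, kind = "token"), ev))
  }
  expect_true(all(diff(covs) >= 0))
  empty <- trajectoryEnsemble(matrix(integer(0), 0, 2), kind = "token")
  expect_error(tokenCoverage(ev, empty), "no tokens")
})
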