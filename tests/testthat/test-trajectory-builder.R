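test_that("configuration dimension follows the velocity weight", {
  sim <- fixtureBranching(seed = 7)
  c0 <- buildConfigurations(sim$table, nPcs = 10, velocityWeight = 0)
  c1 <- buildConfigurations(sim$table, nPcs = 10, velocityWeight = 1)
  expect_equal(ncol(configMatrix(c0)), 10L)
  expect_equal(ncol(configMatrix(c1)), 20L)
  ## weight zero == projected standardized expression only
  expect_equal(configMatrix(c0), configMatrix(c1)[, 1:10], tolerance = 1e-12)
  ## a configuration correlates perfectly with itself
  expect_equal(stats::cor(configMatrix(c1)[3, ], configMatrix(c1)[3, ]), 1.0)
  expect_error(buildConfigurations(sim$table, nPcs = 1000), "exceeds")
})

test_that("zero-variance genes are dropped with a warning", {
  expr <- matrix(rnorm(40), 10, 4)
  expr[, 2] <- 5                                 # constant gene
  meta <- data.frame(cell_id = paste0("c", 1:10), time = rep(0:1, each = 5),
                     cell_type = "a")
  tab <- makeCellTable(expr, expr, meta)
  expect_warning(cfg <- buildConfigurations(tab, nPcs = 2), "zero-variance")
  expect_identical(cfg@droppedGenes, "g2")
})

test_that("candidate sets are next-layer only, clamped, and tie-stable", {
  pipe <- fixturePipeline()
  cfg <- pipe$cfg
  l0 <- which(cfg@layer == 0L); l1 <- which(cfg@layer == 1L)
  cand <- candidateNeighbors(cfg, l0, l1, k = 10)
  expect_true(all(unlist(cand) %in% l1))
  expect_true(all(lengths(cand) == 10L))
  ## k beyond the next layer size: the whole layer, still deterministic
  all40 <- candidateNeighbors(cfg, l0, l1, k = 999)
  expect_true(all(vapply(all40, function(s) setequal(s, l1), logical(1))))
  expect_error(candidateNeighbors(cfg, l0, integer(0), k = 3), "empty")

  ## an identical-configuration cell is always among the candidates
  coords <- cfg@coords
  coords[l1[5], ] <- coords[l0[1], ]
  cfg2 <- cfg; cfg2@coords <- coords
  cand2 <- candidateNeighbors(cfg2, l0, l1, k = 1)
  expect_identical(cand2[[1L]], l1[5])

  ## exact ties broken by ascending cell index
  coords[l1[7], ] <- coords[l1[5], ]
  cfg3 <- cfg; cfg3@coords <- coords
  c3 <- candidateNeighbors(cfg3, l0, l1, k = 1)
  expect_identical(c3[[1L]], min(l1[5], l1[7]))
})

test_that("transition rows are the softmax of configuration correlations", {
  pipe <- fixturePipeline()
  kern <- pipe$kern
  ## every row is a probability vector
  for (t in seq_len(kern@nSteps)) {
    sums <- vapply(kern@probs[[t]], sum, numeric(1))
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(unlist(kern@probs[[t]]) >= 0))
  }
  ## independent recomputation for a sampled row
  cfg <- pipe$cfg
  src <- kern@layers[[2]][4]
  cand <- kern@candidates[[2]][[4]]
  cc <- vapply(cand, function(k) stats::cor(cfg@coords[src, ], cfg@coords[k, ]),
               numeric(1))
  expect_equal(kern@probs[[2]][[4]], exp(cc) / sum(exp(cc)), tolerance = 1e-12)

  ## two-point softmax at corr (1, 0) and the equal-corr uniform case
  expect_equal(trajaction:::softmax(c(1, 0)),
               c(exp(1) / (1 + exp(1)), 1 / (1 + exp(1))), tolerance = 1e-12)
  expect_equal(trajaction:::softmax(rep(0.3, 4)), rep(0.25, 4))
})

test_that("memory weighting reduces to the Markov kernel at lambda = 0", {
  pipe <- fixturePipeline()
  cfg <- pipe$cfg; kern <- pipe$kern
  src <- kern@layers[[2]][1]
  cand <- kern@candidates[[2]][[1]]
  markovRow <- kern@probs[[2]][[1]]
  hist <- c(src, kern@layers[[1]][3])            # most recent first
  expect_lt(max(abs(memoryTransitionProbs(cfg, cand, hist, 0, 5) - markovRow)),
            1e-12)
  ## window L = 1 equals the Markov row for any lambda
  for (lam in c(0, 0.3, 1))
    expect_lt(max(abs(memoryTransitionProbs(cfg, cand, hist, lam, 1) -
                        markovRow)), 1e-12)
  expect_error(memoryTransitionProbs(cfg, cand, integer(0), 0.5, 2), "history")
})

test_that("memory row matches its defining weighted-correlation form", {
  pipe <- fixturePipeline()
  cfg <- pipe$cfg; kern <- pipe$kern
  cand <- kern@candidates[[3]][[2]]
  hist <- c(kern@layers[[3]][2], kern@layers[[2]][5], kern@layers[[1]][1])
  lam <- 0.6; L <- 3
  scores <- numeric(length(cand))
  for (m in 0:(L - 1)) {
    cm <- cfg@coords[hist[m + 1], ]
    scores <- scores + lam^m *
      vapply(cand, function(k) stats::cor(cm, cfg@coords[k, ]), numeric(1))
  }
  expect_equal(memoryTransitionProbs(cfg, cand, hist, lam, L),
               exp(scores - max(scores)) / sum(exp(scores - max(scores))),
               tolerance = 1e-12)
})

test_that("an older state favoring a candidate gains weight with lambda", {
  ## history state 2 is maximally correlated with candidate B; brute-force
  ## over a lambda grid, p(B) must be non-decreasing
  coords <- rbind(
    A  = c(1, 0, 0.5, 0.2),
    B  = c(0, 1, -0.5, 0.3),
    h1 = c(1, 0, 0.45, 0.25),                   # recent: favors A
    h2 = c(0, 1, -0.45, 0.35))                  # older: favors B
  cfg <- methods::new("ConfigurationMatrix", coords = coords,
    layer = c(1L, 1L, 0L, 0L), cellIds = rownames(coords),
    basis = matrix(0, 0, 0), geneMeans = numeric(), geneSds = numeric(),
    droppedGenes = character(), nPcs = 4L, velocityWeight = 0)
  pB <- vapply(seq(0, 1, by = 0.1), function(lam)
    memoryTransitionProbs(cfg, c(1L, 2L), c(3L, 4L), lam, 2)[2L], numeric(1))
  expect_true(all(diff(pB) >= -1e-12))
  expect_gt(pB[11], pB[1])
})

test_that("sampled ensembles are seeded, layer-consistent, and kernel-faithful", {
  pipe <- fixturePipeline()
  ens1 <- sampleTrajectories(pipe$kern, 30, seed = 5, configs = pipe$cfg)
  ens2 <- sampleTrajectories(pipe$kern, 30, seed = 5, configs = pipe$cfg)
  expect_identical(as.matrix(ens1), as.matrix(ens2))
  lay <- pipe$cfg@layer
  paths <- as.matrix(ens1)
  for (t in seq_len(ncol(paths)))
    expect_true(all(lay[paths[, t]] == t - 1L))
})

test_that("a deterministic kernel collapses every trajectory onto one path", {
  ## single layer-0 cell + k = 1 candidates makes each row a point mass
  expr <- matrix(rnorm(5 * 6), 5, 6)
  meta <- data.frame(cell_id = paste0("c", 1:5), time = c(0, 1, 1, 2, 2),
                     cell_type = "a")
  tab <- makeCellTable(expr, expr, meta)
  cfg <- buildConfigurations(tab, nPcs = 2, velocityWeight = 0)
  kern <- markovTransitionProbs(cfg, k = 1)
  ens <- sampleTrajectories(kern, 20, seed = 3)
  expect_equal(nrow(unique(as.matrix(ens))), 1L)
})

test_that("noise-free sampling recovers the designed lineage tree", {
  spec <- lineageSpec(nLayers = 5, cellsPerLayer = 40, nGenes = 30,
    branchPoints = list(list(layer = 2, nBranches = 2, probs = c(0.5, 0.5))),
    noiseSd = 0, driftScale = 1)
  sim <- simulateBranchingProcess(spec, seed = 21)
  cfg <- buildConfigurations(sim$table, nPcs = 5, velocityWeight = 1)
  kern <- markovTransitionProbs(cfg, k = 10)
  ens <- sampleTrajectories(kern, 200, seed = 9, configs = cfg)
  lin <- sim$truth@cells$lineage
  paths <- as.matrix(ens)
  ok <- 0L; tot <- 0L
  for (r in seq_len(nrow(paths))) for (t in seq_len(ncol(paths) - 1L)) {
    tot <- tot + 1L
    if (followsLineage(sim$truth, lin[paths[r, t]], lin[paths[r, t + 1L]], t))
      ok <- ok + 1L
  }
  expect_gt(ok / tot, 0.95)
})
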