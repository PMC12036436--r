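test_that("simulated tables have the designed shape and are seed-stable", {
  spec <- lineageSpec(nLayers = 5, cellsPerLayer = 40, nGenes = 30,
    branchPoints = list(list(layer = 2, nBranches = 2, probs = c(0.5, 0.5))))
  sim <- simulateBranchingProcess(spec, seed = 7)
  expect_equal(ncol(sim$table), 200L)
  expect_equal(nLayers(sim$table), 5L)
  expect_equal(unname(layerSizes(sim$table)), rep(40L, 5))
  expect_equal(nrow(expressionMatrix(sim$table)), 30L)
  expect_equal(dim(velocityMatrix(sim$table)), dim(expressionMatrix(sim$table)))

  again <- simulateBranchingProcess(spec, seed = 7)
  expect_identical(expressionMatrix(again$table), expressionMatrix(sim$table))
  expect_identical(sim$truth@cells, again$truth@cells)
  other <- simulateBranchingProcess(spec, seed = 8)
  expect_false(identical(expressionMatrix(other$table),
                         expressionMatrix(sim$table)))
})

test_that("invalid lineage specs are rejected", {
  expect_error(lineageSpec(5, 10, 5,
    branchPoints = list(list(layer = 4, nBranches = 2, probs = c(0.5, 0.5)))),
    "branch point at layer")
  expect_error(lineageSpec(5, 10, 5,
    branchPoints = list(list(layer = 2, nBranches = 2, probs = c(0.6, 0.6)))),
    "sum to 1")
  expect_error(lineageSpec(5, 10, 5,
    bottleneck = list(layer = 2, survivingFraction = 0)), "survivingFraction")
})

test_that("branch assignment frequencies match the designed probabilities", {
  ## binomial oracle: with 10^4 layer cells and p = 1/2 the standard error
  ## of the branch-1 fraction is sqrt(0.25/1e4) = 0.005, so +/- 0.015 is 3 SE
  spec <- lineageSpec(nLayers = 4, cellsPerLayer = 10000, nGenes = 3,
    branchPoints = list(list(layer = 2, nBranches = 2, probs = c(0.5, 0.5))),
    noiseSd = 0.1)
  sim <- simulateBranchingProcess(spec, seed = 5)
  lin <- sim$truth@cells
  atBranch <- lin$lineage[lin$layer == 2L]
  frac <- mean(atBranch == "root.1")
  expect_lt(abs(frac - 0.5), 0.015)
})

test_that("every non-root cell has a parent in the previous layer", {
  sim <- fixtureBranching(seed = 9)
  cells <- sim$truth@cells
  rownames(cells) <- cells$cell_id
  nonRoot <- cells[cells$layer > 0L, ]
  parents <- cells[nonRoot$parent_cell_id, ]
  expect_true(all(parents$layer == nonRoot$layer - 1L))
  expect_true(all(is.na(cells$parent_cell_id[cells$layer == 0L])))
})

test_that("noise-free branch-layer cohorts collapse to identical states", {
  sim <- fixtureBranching(noiseSd = 0, seed = 4)
  expr <- t(expressionMatrix(sim$table))
  key <- paste(sim$truth@cells$lineage, sim$truth@cells$layer)
  for (k in unique(key)) {
    rows <- expr[key == k, , drop = FALSE]
    expect_lt(max(sweep(rows, 2L, rows[1L, ])), 1e-12)
  }
})

test_that("velocity points along the true lineage direction on average", {
  sim <- fixtureBranching(seed = 7)             # default noise
  expr <- t(expressionMatrix(sim$table))
  vel <- t(velocityMatrix(sim$table))
  cells <- sim$truth@cells
  means <- sim$truth@branchMeans
  children <- sim$truth@children
  cosines <- c()
  for (c in which(cells$layer < max(cells$layer))) {
    lin <- cells$lineage[c]; t <- cells$layer[c]
    kids <- children[[lin]]
    target <- if (!is.null(kids) && kids$layer == t + 1L)
      Reduce(`+`, Map(function(k, p) p * means[[k]][t + 2L, ],
                      kids$labels, kids$probs))
    else means[[lin]][t + 2L, ]
    disp <- target - means[[lin]][t + 1L, ]
    v <- vel[c, ]
    cosines <- c(cosines, sum(v * disp) / sqrt(sum(v^2) * sum(disp^2)))
  }
  expect_gt(mean(cosines), 0)
})
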