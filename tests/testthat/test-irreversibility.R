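test_that("reversal operators satisfy their algebraic identities", {
  expect_equal(reverseTrajectory(c(1L, 2L, 3L)), c(3L, 2L, 1L))
  expect_equal(reverseTrajectory(reverseTrajectory(c(4L, 1L, 2L))), c(4L, 1L, 2L))
  expect_equal(reverseTrajectory(c(1L, 2L, 1L)), c(1L, 2L, 1L))
  expect_error(reverseTrajectory(integer(0)), "empty")

  g <- c(5L, 1L, 4L, 2L, 3L)
  expect_equal(localReverse(g, 2, 2), g)
  expect_equal(localReverse(g, 0, 4), rev(g))
  expect_equal(localReverse(g, 1, 3), c(5L, 2L, 4L, 1L, 3L))
  expect_equal(localReverse(localReverse(g, 1, 3), 1, 3), g)
  expect_error(localReverse(g, 3, 1), "interval")
  expect_error(localReverse(g, 0, 7), "interval")
})

test_that("entropy production is the forward/backward log ratio", {
  ## two-sequence space with p = (0.8, 0.2) swapped by reversal
  m <- markovChainModel(c(0.8, 0.2), rbind(c(0, 1), c(1, 0)), 2)
  expect_equal(entropyProduction(m, c(1L, 2L)), log(4), tolerance = 1e-12)
  expect_equal(entropyProduction(m, c(2L, 1L)), -log(4), tolerance = 1e-12)
  ## detailed balance: an i.i.d. uniform model produces zero entropy
  uni <- uniformModel(5, 4)
  for (rep in 1:10) {
    traj <- sample.int(5, 4, replace = TRUE)
    expect_identical(entropyProduction(uni, traj), 0)
  }
  ## antisymmetry on a generic positive chain
  set.seed(7)
  chain <- randomChainModel(V = 3, len = 5)
  for (rep in 1:20) {
    traj <- sample.int(3, 5, replace = TRUE)
    expect_equal(entropyProduction(chain, rev(traj)),
                 -entropyProduction(chain, traj), tolerance = 1e-12)
  }
})

test_that("local entropy production reduces to its boundary cases", {
  set.seed(8)
  chain <- randomChainModel(V = 3, len = 6)
  traj <- c(1L, 3L, 2L, 2L, 1L, 3L)
  expect_identical(localEntropyProduction(chain, traj, 2, 2), 0)
  expect_equal(localEntropyProduction(chain, traj, 0, 5),
               entropyProduction(chain, traj), tolerance = 1e-12)
  ## direct two-evaluation oracle at every interval
  for (i in 0:5) for (j in i:5) {
    direct <- trajectoryLogProb(chain, traj) -
      trajectoryLogProb(chain, localReverse(traj, i, j))
    if (i == j) direct <- 0
    expect_equal(localEntropyProduction(chain, traj, i, j), direct,
                 tolerance = 1e-12)
  }
})

test_that("expected entropy production equals the forward-backward KL", {
  m <- markovChainModel(c(0.8, 0.2), rbind(c(0, 1), c(1, 0)), 2)
  expect_equal(expectedEntropyProduction(m), 0.6 * log(4), tolerance = 1e-12)
  expect_equal(expectedEntropyProduction(uniformModel(4, 3)), 0,
               tolerance = 1e-12)
  ## two independent code paths agree, and KL is non-negative, on a sweep
  set.seed(9)
  for (rep in 1:100) {
    chain <- randomChainModel(V = 3, len = 3)
    ep <- expectedEntropyProduction(chain)
    expect_equal(ep, klForwardBackward(chain), tolerance = 1e-9)
    expect_gte(ep, -1e-12)
  }
})

test_that("the entropy-production map matches direct recomputation", {
  chain <- fixtureBiasedChain()
  gen <- generateTrajectories(chain, 50, seed = 12)
  m <- epMap(chain, gen$ensemble)
  ## the length-0 column is identically zero with zero variance
  zero <- m[m$length == 0, ]
  expect_true(all(zero$mean_sigma == 0) && all(zero$var_sigma == 0))
  ## each finite cell equals the mean of directly recomputed sigmas
  paths <- as.matrix(gen$ensemble)
  for (r in sample(nrow(m), 10)) {
    i <- m$i[r]; len <- m$length[r]
    sig <- vapply(seq_len(nrow(paths)), function(q)
      localEntropyProduction(chain, paths[q, ], i, i + len), numeric(1))
    expect_equal(m$mean_sigma[r], mean(sig[is.finite(sig)]), tolerance = 1e-12)
  }
})

test_that("mean entropy production grows with segment length on a biased chain", {
  ## closed-form structure: every non-forward transition of the 12-state
  ## drift chain has identical probability, so sigma_{i,j} is (number of
  ## forward transitions disturbed) x log(p_fwd / p_other). Extending a
  ## segment inside the trajectory disturbs one more transition (+cGain);
  ## extending it to the trajectory end disturbs none (flat in expectation).
  chain <- fixtureBiasedChain()
  cGain <- log(0.85) - log(0.15 / 11)
  gen <- generateTrajectories(chain, 400, seed = 13)
  m <- epMap(chain, gen$ensemble)
  expect_true(all(m$n_infinite == 0))            # strictly positive chain
  Tm <- max(m$i)
  for (i in unique(m$i)) {
    sub <- m[m$i == i, ]
    sub <- sub[order(sub$length), ]
    d <- diff(sub$mean_sigma)
    if (length(d) > 1L)
      expect_true(all(d[-length(d)] > 0.5 * cGain))  # interior extensions
    if (length(d) >= 1L)
      expect_gt(d[length(d)], -0.5 * cGain)          # terminal: flat
  }
  ## the full reversal disturbs every transition: sigma ~ (T+1) x cGain
  full <- m$mean_sigma[m$i == 0 & m$length == max(m$length)]
  expect_gt(full, 0.75 * (Tm + 1) * cGain)
})
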