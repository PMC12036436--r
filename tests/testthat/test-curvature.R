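test_that("multipartite graphs count degrees by traversals and stay layered", {
  ## two trajectories sharing exactly one interior node
  ens <- trajectoryEnsemble(rbind(c(1L, 3L, 4L, 6L), c(2L, 3L, 5L, 7L)),
                            kind = "token")
  g <- buildMultipartiteGraph(ens)
  expect_equal(g@multDegree[["3"]], 4)           # 2 in + 2 out
  expect_lte(g@simpleDegree[["3"]], 4)
  ## a cell traversed by 3 trajectories at an interior layer has degree 6
  ens3 <- trajectoryEnsemble(rbind(c(1L, 3L, 4L), c(2L, 3L, 4L), c(1L, 3L, 5L)),
                             kind = "token")
  expect_equal(buildMultipartiteGraph(ens3)@multDegree[["3"]], 6)
  ## every edge joins consecutive layers and bipartiteness kills triangles
  pipe <- fixturePipeline(nTraj = 40)
  gl <- buildMultipartiteGraph(pipe$tok, pipe$vocab)
  lay <- stats::setNames(gl@layer, as.character(gl@nodes))
  expect_true(all(abs(lay[as.character(gl@edges$i)] -
                        lay[as.character(gl@edges$j)]) == 1))
  rep <- curvatureReport(gl, "simple")
  expect_true(all(rep$edges$T_ij == 0))
  expect_error(buildMultipartiteGraph(
    trajectoryEnsemble(matrix(integer(0), 0, 3), kind = "token")), "empty")
})

test_that("layered graphs agree with an igraph reconstruction", {
  skip_if_not_installed("igraph")
  pipe <- fixturePipeline(nTraj = 30)
  g <- buildMultipartiteGraph(pipe$tok, pipe$vocab)
  ig <- igraph::graph_from_data_frame(g@edges[, c("i", "j")],
                                      directed = FALSE,
                                      vertices = data.frame(name = g@nodes))
  expect_true(igraph::is_bipartite(
    igraph::set_vertex_attr(ig, "type", value = g@layer %% 2 == 0)))
  deg <- igraph::degree(ig)
  expect_equal(unname(deg[as.character(g@nodes)]),
               unname(g@simpleDegree[as.character(g@nodes)]))
})

test_that("degree-one edges and the printed small graphs are exact", {
  A <- pathGraph3()
  expect_equal(balancedFormanCurvature(A, 1, 2), 0)
  expect_equal(balancedFormanCurvature(A, 2, 3), 0)
  ## C4: Ric = 1 from the 4-cycle term; K4: Ric = 4/3 from triangles
  C4 <- cycleGraph4()
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))) {
    expect_equal(balancedFormanCurvature(C4, e[1], e[2]), 1.0)
    expect_equal(oracleBalancedForman(C4, e[1], e[2]), 1.0)
  }
  K4 <- completeGraph4()
  expect_equal(balancedFormanCurvature(K4, 1, 2), 4 / 3, tolerance = 1e-12)
  expect_equal(oracleBalancedForman(K4, 1, 2), 4 / 3, tolerance = 1e-12)
  expect_error(balancedFormanCurvature(A, 1, 3), "no edge")
})

test_that("curvature matches brute-force enumeration on random graphs", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    A <- randomAdjacency(n, stats::runif(1, 0.25, 0.6))
    edges <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
    if (!nrow(edges)) next
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      ric <- balancedFormanCurvature(A, i, j)
      expect_identical(ric, oracleBalancedForman(A, i, j))
      ## lower bound: all terms beyond the degree terms are non-negative
      d <- rowSums(A)
      if (min(d[i], d[j]) > 1)
        expect_gte(ric, 2 / d[i] + 2 / d[j] - 2)
    }
  }
})

test_that("node curvature is the (weighted) mean of incident edges", {
  pipe <- fixturePipeline(nTraj = 40)
  g <- buildMultipartiteGraph(pipe$tok, pipe$vocab)
  rep <- curvatureReport(g, "simple", pipe$vocab)
  ## re-summation oracle over the edge table
  for (v in sample(g@nodes, 8)) {
    inc <- rep$edges[rep$edges$i == v | rep$edges$j == v, ]
    expect_equal(rep$nodes$kappa[rep$nodes$token == v],
                 mean(inc$ric), tolerance = 1e-12)
  }
  ## two incident edges with Ric 1 and 0.5 average to 0.75: C4 plus a
  ## pendant vertex attached at node 1
  A <- matrix(0L, 5, 5)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 5)))
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1L
  adj <- stats::setNames(lapply(seq_len(5), function(r) which(A[r, ] != 0)),
                         as.character(1:5))
  rics <- vapply(adj[["2"]], function(j)
    balancedFormanCurvature(A, 2, j), numeric(1))
  expect_equal(mean(rics), mean(c(balancedFormanCurvature(A, 2, 1),
                                  balancedFormanCurvature(A, 2, 3))))
  ## multiplicity mode weights by traversal counts
  ens <- trajectoryEnsemble(rbind(c(1L, 3L, 4L), c(2L, 3L, 4L), c(2L, 3L, 4L)),
                            kind = "token")
  gm <- buildMultipartiteGraph(ens)
  repM <- curvatureReport(gm, "multiplicity")
  e <- repM$edges
  w <- e$multiplicity[e$i == 3 | e$j == 3]
  ric <- e$ric[e$i == 3 | e$j == 3]
  expect_equal(repM$nodes$kappa[repM$nodes$token == 3],
               sum(w * ric) / gm@multDegree[["3"]], tolerance = 1e-12)
})

test_that("the designed bridge edge has the lowest curvature in its layer", {
  g <- buildMultipartiteGraph(fixtureBridgeEnsemble())
  rep <- curvatureReport(g, "simple")
  mid <- rep$edges[rep$edges$layer == 1, ]
  bridge <- mid$i == 2 & mid$j == 11
  expect_true(any(bridge))
  expect_lt(mid$ric[bridge], min(mid$ric[!bridge]))
  ## hub edges inside the dense blocks sit strictly above the bridge
  hub <- mid$i == 3 & mid$j == 8
  expect_gt(mid$ric[hub], mid$ric[bridge])
})
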