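#' Build the multipartite trajectory graph
#'
#' Nodes are the tokens visited by the ensemble (each token carries its time
#' layer); an undirected edge connects two tokens if and only if they are
#' consecutive in at least one trajectory, with integer multiplicity equal
#' to the traversal count. The graph is bipartite between consecutive
#' layers, so it contains no triangles. Both degree notions are recorded:
#' simple degree (distinct neighbors) and multiplicity degree (total
#' traversals in plus out, i.e. the number of trajectories entering or
#' exiting the node).
#'
#' @param ensemble a non-empty token-kind \linkS4class{TrajectoryEnsemble}
#' @param vocab the \linkS4class{Vocabulary} (token layers); optional when
#'   the ensemble tokens are to be layered by position, which is valid
#'   because element t of a trajectory lies in layer t-1
#' @return a \linkS4class{LayeredGraph}
#' @export
buildMultipartiteGraph <- function(ensemble, vocab = NULL) {
  if (nTrajectories(ensemble) == 0L) stopf("ensemble is empty")
  paths <- as.matrix(ensemble)
  L <- ncol(paths)
  tokLayer <- if (!is.null(vocab)) tokenLayer(vocab) else {
    tl <- rep(NA_integer_, max(paths))
    for (t in seq_len(L)) tl[unique(paths[, t])] <- t - 1L
    tl
  }
  pairs <- do.call(rbind, lapply(seq_len(L - 1L), function(t)
    cbind(paths[, t], paths[, t + 1L])))
  i <- pmin(pairs[, 1L], pairs[, 2L]); j <- pmax(pairs[, 1L], pairs[, 2L])
  key <- paste(i, j)
  mult <- base::table(key)
  uk <- names(mult)
  ij <- do.call(rbind, strsplit(uk, " "))
  edges <- data.frame(i = as.integer(ij[, 1L]), j = as.integer(ij[, 2L]),
                      multiplicity = as.integer(mult))
  edges$layer <- pmin(tokLayer[edges$i], tokLayer[edges$j])
  nodes <- sort(unique(c(edges$i, edges$j, as.vector(paths))))
  adj <- stats::setNames(rep(list(integer(0)), length(nodes)),
                         as.character(nodes))
  multDeg <- stats::setNames(numeric(length(nodes)), as.character(nodes))
  for (r in seq_len(nrow(edges))) {
    a <- as.character(edges$i[r]); b <- as.character(edges$j[r])
    adj[[a]] <- c(adj[[a]], edges$j[r]); adj[[b]] <- c(adj[[b]], edges$i[r])
    multDeg[a] <- multDeg[a] + edges$multiplicity[r]
    multDeg[b] <- multDeg[b] + edges$multiplicity[r]
  }
  adj <- lapply(adj, sort)
  methods::new("LayeredGraph", nodes = nodes,
               layer = tokLayer[nodes], adj = adj, edges = edges,
               simpleDegree = stats::setNames(
                 as.numeric(vapply(adj, length, integer(1))), names(adj)),
               multDegree = multDeg)
}

setMethod("show", "LayeredGraph", function(object) {
  cat("LayeredGraph:", length(object@nodes), "nodes,", nrow(object@edges),
      "edges over", length(unique(object@layer)), "layers\n")
})

## Balanced Forman ingredients for an edge of an undirected graph given as
## an adjacency list of integer neighbor vectors (names = node labels).
balancedFormanParts <- function(adj, i, j) {
  ni <- adj[[as.character(i)]]; nj <- adj[[as.character(j)]]
  Tij <- length(intersect(ni, nj))
  ## neighbors forming diagonal-free 4-cycles based at i~j:
  ## k in N(i)\(N(j) u {j}), w in N(k) n N(j), w not in N(i) u {i}
  ks <- setdiff(ni, c(nj, j))
  cyc <- list()
  for (k in ks) {
    ws <- setdiff(intersect(adj[[as.character(k)]], nj), c(ni, i))
    for (w in ws) cyc[[length(cyc) + 1L]] <- as.numeric(c(k, w))
  }
  Si <- length(unique(vapply(cyc, `[`, numeric(1), 1L)))
  Sj <- length(unique(vapply(cyc, `[`, numeric(1), 2L)))
  gammaMax <- if (length(cyc)) max(base::table(unlist(cyc))) else 0
  list(di = as.numeric(length(ni)), dj = as.numeric(length(nj)),
       Tij = as.numeric(Tij), Si = as.numeric(Si), Sj = as.numeric(Sj),
       gammaMax = as.numeric(gammaMax), nCycles = length(cyc))
}

#' Balanced Forman curvature of one edge
#'
#' For an edge i~j of an undirected graph,
#' \deqn{Ric(i,j) = \frac{2}{d_i} + \frac{2}{d_j} - 2
#'   + 2\frac{T_{ij}}{\max(d_i,d_j)} + \frac{T_{ij}}{\min(d_i,d_j)}
#'   + \frac{S_i + S_j}{\gamma_{max}\,\max(d_i,d_j)}}
#' where \eqn{T_{ij}} counts triangles on the edge, \eqn{S_i} the neighbors
#' of i lying on a diagonal-free 4-cycle through i~j, and
#' \eqn{\gamma_{max}} the maximal number of such 4-cycles traversing one
#' common node; the 4-cycle term is 0 when \eqn{\gamma_{max} = 0}, and
#' \eqn{Ric(i,j) := 0} when \eqn{\min(d_i, d_j) = 1}. Negative values mark
#' bridges/bottlenecks (oversquashing), positive values mark hubs.
#'
#' @param adjacency a symmetric 0/1 (or logical) adjacency matrix, or an
#'   adjacency list of integer neighbor vectors named by node
#' @param i,j node labels of an existing edge
#' @param degrees optional named degree vector overriding the simple
#'   degrees (used for multiplicity-degree mode)
#' @return the curvature, a real > -2
#' @export
balancedFormanCurvature <- function(adjacency, i, j, degrees = NULL) {
  adj <- if (is.matrix(adjacency)) {
    nm <- if (is.null(rownames(adjacency))) seq_len(nrow(adjacency)) else rownames(adjacency)
    stats::setNames(lapply(seq_len(nrow(adjacency)), function(r)
      which(adjacency[r, ] != 0)), nm)
  } else adjacency
  if (!(j %in% adj[[as.character(i)]]))
    stopf("no edge between %s and %s", i, j)
  parts <- balancedFormanParts(adj, i, j)
  di <- if (is.null(degrees)) parts$di else degrees[[as.character(i)]]
  dj <- if (is.null(degrees)) parts$dj else degrees[[as.character(j)]]
  if (min(di, dj) == 1) return(0)
  ric <- 2 / di + 2 / dj - 2 + 2 * parts$Tij / max(di, dj) +
    parts$Tij / min(di, dj)
  if (parts$gammaMax > 0)
    ric <- ric + (parts$Si + parts$Sj) / (parts$gammaMax * max(di, dj))
  ric
}

#' Balanced Forman curvature of a trajectory-graph edge
#'
#' @param graph a \linkS4class{LayeredGraph}
#' @param i,j token ids of an existing edge
#' @param degreeMode "simple" (distinct-neighbor degrees; standard) or
#'   "multiplicity" (degrees = total trajectory traversals, the
#'   trajectory-count reading of the node degree)
#' @return the edge curvature
#' @export
edgeCurvature <- function(graph, i, j, degreeMode = c("simple", "multiplicity")) {
  degreeMode <- match.arg(degreeMode)
  deg <- if (degreeMode == "simple") NULL else graph@multDegree
  balancedFormanCurvature(graph@adj, i, j, degrees = deg)
}

#' Node curvature: mean curvature of incident edges
#'
#' \deqn{\kappa_i = \frac{1}{d_i} \sum_{j:(i,j) \in E} Ric(i,j)}
#' In multiplicity mode each edge term is weighted by its traversal
#' multiplicity and \eqn{d_i} is the multiplicity degree.
#'
#' @inheritParams edgeCurvature
#' @param node token id with at least one incident edge
#' @return the node curvature kappa
#' @export
nodeCurvature <- function(graph, node, degreeMode = c("simple", "multiplicity")) {
  degreeMode <- match.arg(degreeMode)
  nb <- graph@adj[[as.character(node)]]
  if (!length(nb)) stopf("node %s is isolated", node)
  rics <- vapply(nb, function(j) edgeCurvature(graph, node, j, degreeMode),
                 numeric(1))
  if (degreeMode == "simple") return(mean(rics))
  e <- graph@edges
  w <- vapply(nb, function(j) {
    r <- which((e$i == node & e$j == j) | (e$i == j & e$j == node))
    e$multiplicity[r]
  }, integer(1))
  sum(w * rics) / graph@multDegree[[as.character(node)]]
}

#' Full per-edge and per-node curvature report
#'
#' @inheritParams edgeCurvature
#' @param vocab optional \linkS4class{Vocabulary} to attach cell types
#' @return \code{list(edges =, nodes =)} data.frames: per edge (i, j, layer,
#'   d_i, d_j, T_ij, S_i, S_j, gamma_max, ric) and per node (token, layer,
#'   cell_type, kappa)
#' @export
curvatureReport <- function(graph, degreeMode = c("simple", "multiplicity"),
                            vocab = NULL) {
  degreeMode <- match.arg(degreeMode)
  deg <- if (degreeMode == "simple") graph@simpleDegree else graph@multDegree
  e <- graph@edges
  parts <- lapply(seq_len(nrow(e)), function(r)
    balancedFormanParts(graph@adj, e$i[r], e$j[r]))
  edges <- data.frame(
    i = e$i, j = e$j, layer = e$layer, multiplicity = e$multiplicity,
    d_i = vapply(seq_len(nrow(e)), function(r) deg[[as.character(e$i[r])]], numeric(1)),
    d_j = vapply(seq_len(nrow(e)), function(r) deg[[as.character(e$j[r])]], numeric(1)),
    T_ij = vapply(parts, `[[`, numeric(1), "Tij"),
    S_i = vapply(parts, `[[`, numeric(1), "Si"),
    S_j = vapply(parts, `[[`, numeric(1), "Sj"),
    gamma_max = vapply(parts, `[[`, numeric(1), "gammaMax"))
  edges$ric <- vapply(seq_len(nrow(e)), function(r)
    edgeCurvature(graph, e$i[r], e$j[r], degreeMode), numeric(1))
  nodes <- data.frame(
    token = graph@nodes, layer = graph@layer,
    cell_type = if (is.null(vocab)) NA_character_ else tokenType(vocab)[graph@nodes],
    kappa = vapply(graph@nodes, function(v)
      nodeCurvature(graph, v, degreeMode), numeric(1)))
  list(edges = edges, nodes = nodes)
}
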