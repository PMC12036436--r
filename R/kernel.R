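#' K-nearest next-layer candidates for every cell of a layer
#'
#' For each layer-t cell, the k nearest layer-(t+1) cells by Euclidean
#' distance in configuration space; if the next layer has fewer than k cells
#' they are all kept. Ties at the k-th distance are broken by ascending cell
#' index, so candidate sets are deterministic.
#'
#' @param configs a \linkS4class{ConfigurationMatrix}
#' @param layerT,layerT1 integer vectors of global cell indices for layer t
#'   and layer t+1 (e.g. from the configuration's \code{layer} slot)
#' @param k candidate-set size (>= 1)
#' @return list (one per layer-t cell, in order) of integer candidate indices
#' @export
candidateNeighbors <- function(configs, layerT, layerT1, k) {
  stopifnot(k >= 1)
  if (!length(layerT1)) stopf("next layer is empty")
  X <- configs@coords[layerT, , drop = FALSE]
  Y <- configs@coords[layerT1, , drop = FALSE]
  kEff <- min(as.integer(k), nrow(Y))
  ## squared Euclidean distances, layerT x layerT1
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  lapply(seq_along(layerT), function(i) {
    ord <- order(d2[i, ], layerT1)           # distance, then cell index
    layerT1[ord[seq_len(kEff)]]
  })
}

## Softmax over exp(corr) for one source cell and its candidate set.
softmaxCorrRow <- function(configs, j, cand) {
  cj <- configs@coords[j, ]
  cc <- vapply(cand, function(k) corrOrZero(cj, configs@coords[k, ]), numeric(1))
  softmax(cc)
}

#' Markovian transition kernel over consecutive layers
#'
#' For every time step t < T and every layer-t cell j with candidate set N_j,
#' the transition probability to candidate k is
#' \deqn{p_{j,k} = \exp(corr(C_j, C_k)) / \sum_{l \in N_j} \exp(corr(C_j, C_l))}
#' with corr the Pearson correlation of the configuration vectors (defined
#' as 0, with a warning, when a configuration is constant). Rows are
#' probability vectors within 1e-12.
#'
#' @param configs a \linkS4class{ConfigurationMatrix}
#' @param k candidate-set size of the KNN search
#' @param candidates optionally, precomputed per-step candidate lists (as
#'   produced internally); when supplied, \code{k} is ignored
#' @return a \linkS4class{TransitionKernel}
#' @export
markovTransitionProbs <- function(configs, k = 30L, candidates = NULL) {
  lay <- configs@layer
  Tmax <- max(lay)
  layers <- lapply(seq(0L, Tmax), function(t) which(lay == t))
  if (is.null(candidates)) {
    candidates <- lapply(seq_len(Tmax), function(t)
      candidateNeighbors(configs, layers[[t]], layers[[t + 1L]], k))
  }
  probs <- lapply(seq_len(Tmax), function(t) {
    src <- layers[[t]]
    lapply(seq_along(src), function(i) {
      cand <- candidates[[t]][[i]]
      if (!length(cand)) stopf("empty candidate set for cell %d", src[i])
      softmaxCorrRow(configs, src[i], cand)
    })
  })
  methods::new("TransitionKernel", candidates = candidates, probs = probs,
               layers = layers, nSteps = as.integer(Tmax))
}

#' Memory-weighted transition probabilities for one step
#'
#' The history-aware transition row over a candidate set N_j:
#' \deqn{p_{j,k} \propto \exp\left(\sum_{m=0}^{L-1} \lambda^m\,
#'   corr(C_{t-1-m}, C_k)\right)}
#' where \code{history} lists the previously visited cells most recent first
#' (its first element is the current cell C_{t-1}); terms reaching before the
#' start of the trajectory are skipped, and \eqn{\lambda^0 = 1} including at
#' \eqn{\lambda = 0}, so \code{lambda = 0} (or \code{L = 1}) reduces exactly
#' to the Markovian row.
#'
#' @param configs a \linkS4class{ConfigurationMatrix}
#' @param candidates integer vector of candidate cell indices
#' @param history integer vector of visited cells, most recent first
#' @param lambda memory decay in [0, 1]
#' @param L history window (number of past states considered)
#' @return numeric probability vector over \code{candidates}
#' @export
memoryTransitionProbs <- function(configs, candidates, history, lambda, L) {
  if (!length(history)) stopf("history must contain at least the current cell")
  if (lambda < 0 || lambda > 1) stopf("lambda must be in [0, 1]")
  L <- min(as.integer(L), length(history))
  scores <- numeric(length(candidates))
  for (m in seq(0L, L - 1L)) {
    w <- if (m == 0L) 1 else lambda^m
    cm <- configs@coords[history[m + 1L], ]
    scores <- scores + w * vapply(candidates, function(k)
      corrOrZero(cm, configs@coords[k, ]), numeric(1))
  }
  softmax(scores)
}

#' Sample a trajectory ensemble from a transition kernel
#'
#' Each trajectory starts at a uniformly drawn layer-0 cell and draws each
#' successive cell from the transition row of its current cell. With
#' \code{lambda > 0} and \code{memoryWindow > 1} the row is re-computed per
#' step from the visited history with [memoryTransitionProbs()] (requires
#' \code{configs}); otherwise the Markovian kernel rows are used directly.
#' Element t of every trajectory lies in layer t-1.
#'
#' @param kernel a \linkS4class{TransitionKernel}
#' @param n number of trajectories (>= 1)
#' @param seed integer seed (deterministic output)
#' @param configs \linkS4class{ConfigurationMatrix}, needed for memory mode
#' @param lambda memory decay in [0, 1] (default 0 = Markov)
#' @param memoryWindow history window L (default 1 = Markov)
#' @return a cell-kind \linkS4class{TrajectoryEnsemble}
#' @export
sampleTrajectories <- function(kernel, n, seed = 0L, configs = NULL,
                               lambda = 0, memoryWindow = 1L) {
  stopifnot(n >= 1)
  useMemory <- lambda > 0 && memoryWindow > 1L
  if (useMemory && is.null(configs))
    stopf("memory-weighted sampling needs the configuration matrix")
  set.seed(stageSeed(seed, "sample-trajectories"))
  Tmax <- kernel@nSteps
  paths <- matrix(0L, n, Tmax + 1L)
  l0 <- kernel@layers[[1L]]
  for (i in seq_len(n)) {
    cur <- l0[sample.int(length(l0), 1L)]
    paths[i, 1L] <- cur
    hist <- cur
    for (t in seq_len(Tmax)) {
      pos <- match(cur, kernel@layers[[t]])
      cand <- kernel@candidates[[t]][[pos]]
      p <- if (useMemory)
        memoryTransitionProbs(configs, cand, rev(hist), lambda, memoryWindow)
      else kernel@probs[[t]][[pos]]
      cur <- cand[sample.int(length(cand), 1L, prob = p)]
      paths[i, t + 1L] <- cur
      hist <- c(hist, cur)
    }
  }
  ids <- if (!is.null(configs)) configs@cellIds else character()
  methods::new("TrajectoryEnsemble", paths = paths, kind = "cell", ids = ids)
}

#' Per-step row-entropy quantiles of a kernel (summary table)
#'
#' @param kernel a \linkS4class{TransitionKernel}
#' @return data.frame with step and row-entropy quantiles (nats)
#' @export
kernelSummary <- function(kernel) {
  do.call(rbind, lapply(seq_len(kernel@nSteps), function(t) {
    h <- vapply(kernel@probs[[t]], shannon, numeric(1))
    q <- stats::quantile(h, c(0.25, 0.5, 0.75))
    data.frame(step = t - 1L, q25 = q[[1]], median = q[[2]], q75 = q[[3]])
  }))
}
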