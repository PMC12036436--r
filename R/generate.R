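#' Nucleus (top-k / top-p / temperature) filtering of a distribution
#'
#' Applies, in this order: temperature scaling (p proportional to
#' p^(1/T)), top-k truncation (keep the k most likely entries), and top-p
#' truncation (keep the smallest probability-sorted prefix whose cumulative
#' mass reaches at least topP), then renormalizes the survivors. Removed
#' entries are exactly 0. Ties at the top-k/top-p boundary are broken by
#' ascending token id, so the filter is deterministic. The default settings
#' (unlimited top-k, topP = 1, T = 1) return the input unchanged.
#'
#' @param probs a probability vector
#' @param settings a \linkS4class{SamplerSettings}
#' @return a filtered probability vector of the same length
#' @export
nucleusFilter <- function(probs, settings = samplerSettings()) {
  assertProb(probs, what = "probs")
  methods::validObject(settings)
  p <- probs
  if (settings@temperature != 1) {
    w <- ifelse(p > 0, p^(1 / settings@temperature), 0)
    p <- w / sum(w)
  }
  ord <- order(-p, seq_along(p))            # prob desc, token id asc
  keep <- rep(FALSE, length(p))
  kTop <- min(settings@topK, sum(p > 0))
  inK <- ord[seq_len(kTop)]
  pk <- p[inK] / sum(p[inK])
  cum <- cumsum(pk)
  nNucleus <- which(cum >= settings@topP - 1e-12)[1L]
  keep[inK[seq_len(nNucleus)]] <- TRUE
  p[!keep] <- 0
  p / sum(p)
}

#' Generate trajectories from a trained model with nucleus sampling
#'
#' Samples \code{n} full-length token sequences stepwise: at every position
#' the model's next-token distribution is passed through [nucleusFilter()]
#' and a token is drawn. With \code{recordDistributions = TRUE} the
#' per-step *unfiltered* model distributions of every trajectory are
#' returned alongside (used by the metrics modules). Fixed seed gives
#' identical output; \code{topK = 1} degenerates to the greedy path.
#'
#' @param model a trained \linkS4class{ARModel}
#' @param n number of trajectories (>= 1)
#' @param settings a \linkS4class{SamplerSettings}
#' @param seed integer seed
#' @param recordDistributions logical
#' @return \code{list(ensemble = token TrajectoryEnsemble,
#'   distributions = NULL | list of step x vocab matrices)}
#' @export
generateTrajectories <- function(model, n, settings = samplerSettings(),
                                 seed = 0L, recordDistributions = FALSE) {
  stopifnot(n >= 1)
  set.seed(stageSeed(seed, "generate"))
  L <- seqLength(model); V <- vocabSize(model)
  paths <- matrix(0L, n, L)
  dists <- if (recordDistributions) vector("list", n) else NULL
  for (i in seq_len(n)) {
    prefix <- integer(0)
    di <- if (recordDistributions) matrix(0, L, V) else NULL
    for (t in seq_len(L)) {
      d0 <- nextDistribution(model, prefix)
      if (recordDistributions) di[t, ] <- d0
      pf <- nucleusFilter(d0, settings)
      tok <- sample.int(V, 1L, prob = pf)
      prefix <- c(prefix, tok)
    }
    paths[i, ] <- prefix
    if (recordDistributions) dists[[i]] <- di
  }
  list(ensemble = methods::new("TrajectoryEnsemble", paths = paths,
                               kind = "token", ids = character()),
       distributions = dists)
}
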