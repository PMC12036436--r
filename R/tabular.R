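#' Fit the empirical back-off autoregressive model
#'
#' Conditional next-token distributions are the empirical frequencies of the
#' training ensemble given the last up-to-\code{maxOrder} tokens; an unseen
#' context backs off to the longest seen suffix and ultimately to the
#' per-position (layer-wise) marginal. For a context seen in training the
#' returned distribution equals the count ratios exactly, making this the
#' exact chain-rule oracle on its own training data.
#'
#' @param ensemble a non-empty token-kind \linkS4class{TrajectoryEnsemble}
#' @param maxOrder maximal context order (>= 0)
#' @param vocabSize vocabulary size (defaults to the max token seen)
#' @return a \linkS4class{TabularARModel}
#' @export
fitTabular <- function(ensemble, maxOrder = 2L, vocabSize = NULL) {
  if (nTrajectories(ensemble) == 0L) stopf("ensemble is empty")
  paths <- as.matrix(ensemble)
  V <- if (is.null(vocabSize)) max(paths) else as.integer(vocabSize)
  L <- ncol(paths)
  counts <- new.env(parent = emptyenv())
  bump <- function(key, tok) {
    cur <- counts[[key]]
    if (is.null(cur)) cur <- numeric(V)
    cur[tok] <- cur[tok] + 1
    counts[[key]] <- cur
  }
  margCounts <- lapply(seq_len(L), function(i) numeric(V))
  for (r in seq_len(nrow(paths))) {
    seqr <- paths[r, ]
    for (t in seq_len(L)) {
      margCounts[[t]][seqr[t]] <- margCounts[[t]][seqr[t]] + 1
      if (t >= 2L && maxOrder >= 1L) {
        for (o in seq_len(min(maxOrder, t - 1L))) {
          key <- paste(seqr[(t - o):(t - 1L)], collapse = ",")
          bump(key, seqr[t])
        }
      }
    }
  }
  contexts <- as.list(counts)
  contexts <- lapply(contexts, function(v) v / sum(v))
  marginals <- lapply(margCounts, function(v) v / sum(v))
  methods::new("TabularARModel", vocabSize = V, seqLength = L,
               maxOrder = as.integer(maxOrder), contexts = contexts,
               marginals = marginals)
}

#' @rdname nextDistribution
#' @export
setMethod("nextDistribution", "TabularARModel", function(model, prefix) {
  t <- length(prefix) + 1L
  if (t > 1L && model@maxOrder >= 1L) {
    for (o in seq(min(model@maxOrder, t - 1L), 1L)) {
      key <- paste(utils::tail(prefix, o), collapse = ",")
      p <- model@contexts[[key]]
      if (!is.null(p)) return(p)
    }
  }
  if (t <= length(model@marginals)) return(model@marginals[[t]])
  rep(1 / model@vocabSize, model@vocabSize)
})

#' @rdname stepDistributions
#' @export
setMethod("stepDistributions", "ARModel", function(model, tokens) {
  t(vapply(seq_along(tokens), function(t)
    nextDistribution(model, tokens[seq_len(t - 1L)]),
    numeric(model@vocabSize)))
})

#' @rdname armodelAccessors
#' @export
setMethod("vocabSize", "ARModel", function(model) model@vocabSize)

#' Accessors for autoregressive models
#'
#' \code{vocabSize}: number of tokens the model predicts over;
#' \code{seqLength}: the trajectory length it was fitted on;
#' \code{trainingLog}: per-epoch metrics of a trained transformer.
#'
#' @param model an \linkS4class{ARModel}
#' @name armodelAccessors
NULL

#' @rdname armodelAccessors
#' @export
setMethod("seqLength", "ARModel", function(model) model@seqLength)

setMethod("show", "TabularARModel", function(object) {
  cat("TabularARModel: vocab", object@vocabSize, ", order", object@maxOrder,
      ",", length(object@contexts), "contexts\n")
})

#' Exact first-order Markov chain as a tabular model
#'
#' Builds a \linkS4class{TabularARModel} whose conditional distributions are
#' given exactly (not estimated): the first step follows \code{init} and
#' every later step row \code{trans[previous token, ]}. Useful as an
#' analytically known process for irreversibility checks.
#'
#' @param init initial distribution over tokens
#' @param trans row-stochastic transition matrix
#' @param len trajectory length
#' @return a \linkS4class{TabularARModel}
#' @export
markovChainModel <- function(init, trans, len) {
  V <- length(init)
  stopifnot(nrow(trans) == V, ncol(trans) == V)
  assertProb(init, what = "init")
  for (i in seq_len(V)) assertProb(trans[i, ], what = sprintf("trans[%d,]", i))
  contexts <- stats::setNames(lapply(seq_len(V), function(i) trans[i, ]),
                              as.character(seq_len(V)))
  marginals <- vector("list", len)
  marginals[[1L]] <- init
  for (t in seq_len(len - 1L))
    marginals[[t + 1L]] <- as.numeric(marginals[[t]] %*% trans)
  methods::new("TabularARModel", vocabSize = as.integer(V),
               seqLength = as.integer(len), maxOrder = 1L,
               contexts = contexts, marginals = marginals)
}

#' I.i.d. uniform next-token model
#'
#' Assigns probability 1/V to every token at every step: a time-reversal
#' symmetric (detailed-balance) reference model under which every
#' trajectory and its reverse are equally likely.
#'
#' @param vocabSize number of tokens V
#' @param len trajectory length
#' @return a \linkS4class{TabularARModel}
#' @export
uniformModel <- function(vocabSize, len) {
  V <- as.integer(vocabSize)
  methods::new("TabularARModel", vocabSize = V, seqLength = as.integer(len),
               maxOrder = 0L, contexts = list(),
               marginals = rep(list(rep(1 / V, V)), len))
}
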