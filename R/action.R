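#' Trajectory log-probability under an autoregressive model
#'
#' The chain-rule sum \eqn{\sum_t \log p_\theta(token_t | tokens_{<t})}; the
#' first term uses the model's empty-prefix distribution. A zero-probability
#' step yields \code{-Inf} (flagged downstream by the irreversibility maps).
#'
#' @param model an \linkS4class{ARModel}
#' @param trajectory integer token vector
#' @return a real <= 0 (possibly \code{-Inf})
#' @export
trajectoryLogProb <- function(model, trajectory) {
  if (any(trajectory < 1L) || any(trajectory > vocabSize(model)))
    stopf("trajectory tokens outside the vocabulary")
  dists <- stepDistributions(model, trajectory)
  p <- dists[cbind(seq_along(trajectory), trajectory)]
  if (any(p <= 0)) return(-Inf)
  sum(log(p))
}

#' Action of a trajectory
#'
#' The action functional is the surprise of the trajectory under the model,
#' \eqn{A_\theta(\gamma) = -\log p_\theta(\gamma)} (in nats); it is
#' non-negative, and \code{+Inf} for zero-probability trajectories. Minimal
#' action paths are the model's most probable (geodesic) trajectories.
#'
#' @inheritParams trajectoryLogProb
#' @return a real >= 0 (possibly \code{+Inf})
#' @export
trajectoryAction <- function(model, trajectory) -trajectoryLogProb(model, trajectory)

#' Mean action over a trajectory ensemble (training loss)
#'
#' The ensemble average \eqn{-(1/N)\sum_i \log p_\theta(\gamma_i)}: the
#' empirical estimate of the trajectory entropy and exactly the
#' cross-entropy loss minimized during training.
#'
#' @param model an \linkS4class{ARModel}
#' @param ensemble a non-empty token-kind \linkS4class{TrajectoryEnsemble}
#' @return mean action in nats per trajectory
#' @export
ensembleEntropy <- function(model, ensemble) {
  if (nTrajectories(ensemble) == 0L) stopf("ensemble is empty")
  paths <- as.matrix(ensemble)
  mean(vapply(seq_len(nrow(paths)), function(i)
    trajectoryAction(model, paths[i, ]), numeric(1)))
}

## All token sequences of a given length (guard: at most `guard` sequences).
enumerateSequences <- function(V, len, guard = 1e6) {
  if (V^len > guard)
    stopf("enumeration of %d^%d sequences exceeds the %g-sequence guard",
          V, len, guard)
  as.matrix(expand.grid(rep(list(seq_len(V)), len)))[, len:1, drop = FALSE]
}

#' Exact model trajectory entropy by exhaustive enumeration
#'
#' Enumerates every token sequence of length \code{maxLen} and returns both
#' the Shannon entropy \eqn{H_\theta = -\sum_\gamma p_\theta(\gamma)\log
#' p_\theta(\gamma)} and, computed independently, the expected action
#' \eqn{\sum_\gamma p_\theta(\gamma) A_\theta(\gamma)}; the two are equal
#' identities and cross-checked within 1e-9. Enumeration is guarded at 1e6
#' sequences.
#'
#' @param model an \linkS4class{ARModel}
#' @param maxLen sequence length to enumerate
#' @return \code{list(entropy =, expectedAction =)}
#' @export
modelTrajectoryEntropy <- function(model, maxLen) {
  seqs <- enumerateSequences(vocabSize(model), maxLen)
  logp <- vapply(seq_len(nrow(seqs)), function(i)
    trajectoryLogProb(model, seqs[i, ]), numeric(1))
  p <- exp(logp)
  pos <- p > 0
  H <- -sum(p[pos] * logp[pos])
  act <- vapply(which(pos), function(i)
    trajectoryAction(model, seqs[i, ]), numeric(1))
  EA <- sum(p[pos] * act)
  if (abs(H - EA) > 1e-9)
    warning("entropy and expected action disagree beyond 1e-9", call. = FALSE)
  list(entropy = H, expectedAction = EA)
}

#' Prediction accuracy of a model on an ensemble
#'
#' For every position after the first, take the argmax next-token
#' prediction (ties to the lowest token id) and report two rates: the
#' fraction whose predicted token lies in the correct time layer
#' (\code{layerOrder}), and the fraction exactly equal to the true next
#' token (\code{exact}).
#'
#' @param model an \linkS4class{ARModel}
#' @param ensemble token-kind evaluation ensemble
#' @param vocab a \linkS4class{Vocabulary} (for token layers); when missing,
#'   layer-order accuracy is NA
#' @return \code{list(exact =, layerOrder =)}
#' @export
sequenceAccuracy <- function(model, ensemble, vocab = NULL) {
  if (nTrajectories(ensemble) == 0L) stopf("ensemble is empty")
  paths <- as.matrix(ensemble)
  nOk <- 0L; nLayerOk <- 0L; nTot <- 0L
  for (i in seq_len(nrow(paths))) {
    dists <- stepDistributions(model, paths[i, ])
    for (t in seq(2L, ncol(paths))) {
      pred <- which.max(dists[t, ])
      nTot <- nTot + 1L
      if (pred == paths[i, t]) nOk <- nOk + 1L
      if (!is.null(vocab) &&
          vocab@tokenLayer[pred] == vocab@tokenLayer[paths[i, t]])
        nLayerOk <- nLayerOk + 1L
    }
  }
  list(exact = nOk / nTot,
       layerOrder = if (is.null(vocab)) NA_real_ else nLayerOk / nTot)
}

#' Token coverage of a generated ensemble
#'
#' The order-independent fraction of evaluation tokens that appear anywhere
#' in the generated ensemble:
#' |generated tokens intersect eval tokens| / |eval tokens|.
#'
#' @param generated,evalEnsemble token-kind ensembles under one vocabulary
#' @return real in [0, 1]
#' @export
tokenCoverage <- function(generated, evalEnsemble) {
  evalTok <- unique(as.vector(as.matrix(evalEnsemble)))
  if (!length(evalTok)) stopf("evaluation ensemble has no tokens")
  genTok <- unique(as.vector(as.matrix(generated)))
  length(intersect(genTok, evalTok)) / length(evalTok)
}
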