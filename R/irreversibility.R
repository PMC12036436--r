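## Entropy production of forward versus (locally) time-reversed
## trajectories. k_B = 1 throughout, so all values are in nats.

#' Reverse a trajectory
#' @param trajectory integer token vector (non-empty)
#' @return the fully reversed trajectory
#' @export
reverseTrajectory <- function(trajectory) {
  if (!length(trajectory)) stopf("trajectory is empty")
  rev(trajectory)
}

#' Locally time-reverse the segment [i, j] of a trajectory
#'
#' Positions before i and after j are unchanged; positions i..j (inclusive,
#' 0-based like the time steps) are reversed in place. \code{i == j} returns
#' the trajectory unchanged, and \code{(0, T)} equals the full reversal.
#'
#' @param trajectory integer token vector
#' @param i,j segment bounds, 0 <= i <= j <= T
#' @return the locally reversed trajectory
#' @export
localReverse <- function(trajectory, i, j) {
  Tm <- length(trajectory) - 1L
  if (i > j || i < 0L || j > Tm)
    stopf("invalid reversal interval [%d, %d] for a trajectory on 0..%d", i, j, Tm)
  out <- trajectory
  out[(i + 1L):(j + 1L)] <- rev(trajectory[(i + 1L):(j + 1L)])
  out
}

#' Entropy production of a trajectory
#'
#' \deqn{\sigma(\gamma) = k_B [\log p_\theta(\gamma) -
#'   \log p_\theta(\tilde\gamma)]}, with \eqn{\tilde\gamma} the full
#' reversal and \eqn{k_B = 1}. Zero under detailed balance (forward and
#' reverse equally likely); \code{+Inf} when the reversal has probability 0
#' (flagged and excluded from ensemble means downstream);
#' antisymmetric: \eqn{\sigma(\tilde\gamma) = -\sigma(\gamma)}.
#'
#' @param model an \linkS4class{ARModel} able to score any token sequence
#' @param trajectory integer token vector
#' @return a real (possibly infinite)
#' @export
entropyProduction <- function(model, trajectory) {
  trajectoryLogProb(model, trajectory) -
    trajectoryLogProb(model, reverseTrajectory(trajectory))
}

#' Local entropy production of a segment
#'
#' \deqn{\sigma_{i,j}(\gamma) = k_B [\log p_\theta(\gamma) -
#'   \log p_\theta(\tilde\gamma[i,j])]}: exactly 0 for \code{i == j} and
#' equal to [entropyProduction()] at \code{(0, T)}.
#'
#' @inheritParams entropyProduction
#' @param i,j reversal interval, 0 <= i <= j <= T
#' @return a real (possibly infinite)
#' @export
localEntropyProduction <- function(model, trajectory, i, j) {
  if (i == j) return(0)
  trajectoryLogProb(model, trajectory) -
    trajectoryLogProb(model, localReverse(trajectory, i, j))
}

#' Expected entropy production
#'
#' Either the exact enumeration
#' \deqn{\langle\sigma\rangle = k_B \sum_\gamma p_\theta(\gamma)
#'   \log[p_\theta(\gamma)/p_\theta(\tilde\gamma)]}
#' over every sequence of the model's length (equal to the KL divergence
#' between the forward and backward trajectory distributions, see
#' [klForwardBackward()]), or, given an ensemble, the sample mean of
#' \eqn{\sigma} with infinite values excluded (their count is reported in
#' the \code{nInfinite} attribute).
#'
#' @param model an \linkS4class{ARModel}
#' @param ensemble optional token \linkS4class{TrajectoryEnsemble}; when
#'   missing, exhaustive enumeration is used (guarded at 1e6 sequences)
#' @return expected entropy production in nats
#' @export
expectedEntropyProduction <- function(model, ensemble = NULL) {
  if (is.null(ensemble)) {
    seqs <- enumerateSequences(vocabSize(model), seqLength(model))
    tot <- 0
    for (r in seq_len(nrow(seqs))) {
      lp <- trajectoryLogProb(model, seqs[r, ])
      if (lp == -Inf) next
      tot <- tot + exp(lp) * (lp - trajectoryLogProb(model, rev(seqs[r, ])))
    }
    return(tot)
  }
  paths <- as.matrix(ensemble)
  sig <- vapply(seq_len(nrow(paths)), function(r)
    entropyProduction(model, paths[r, ]), numeric(1))
  fin <- is.finite(sig)
  out <- mean(sig[fin])
  attr(out, "nInfinite") <- sum(!fin)
  out
}

#' KL divergence between forward and backward trajectory distributions
#'
#' Independent code path for the identity expected entropy production =
#' k_B D_KL(forward || backward): builds the full probability vectors over
#' all enumerable sequences, with the backward probability of a sequence
#' defined as the forward probability of its reversal, and sums
#' \eqn{\sum P \log(P/Q)} directly.
#'
#' @param model an \linkS4class{ARModel}
#' @return the KL divergence in nats
#' @export
klForwardBackward <- function(model) {
  seqs <- enumerateSequences(vocabSize(model), seqLength(model))
  logP <- vapply(seq_len(nrow(seqs)), function(r)
    trajectoryLogProb(model, seqs[r, ]), numeric(1))
  logQ <- vapply(seq_len(nrow(seqs)), function(r)
    trajectoryLogProb(model, rev(seqs[r, ])), numeric(1))
  keep <- logP > -Inf
  sum(exp(logP[keep]) * (logP[keep] - logQ[keep]))
}

#' Local entropy-production map over an ensemble
#'
#' For every start index i and segment length len = j - i, the mean and
#' variance of \eqn{\sigma_{i,j}} across the ensemble; infinite values
#' (zero-probability reversals) are excluded, with the finite count
#' reported per cell rather than imputed. The length-0 column is
#' identically 0.
#'
#' @param model an \linkS4class{ARModel}
#' @param ensemble non-empty token \linkS4class{TrajectoryEnsemble}
#' @param maxLength largest segment length to evaluate (default: full)
#' @return data.frame with columns i, length, mean_sigma, var_sigma,
#'   n_finite, n_infinite
#' @export
epMap <- function(model, ensemble, maxLength = NULL) {
  if (nTrajectories(ensemble) == 0L) stopf("ensemble is empty")
  paths <- as.matrix(ensemble)
  Tm <- ncol(paths) - 1L
  if (is.null(maxLength)) maxLength <- Tm
  ## cache forward log-probs once
  fwd <- vapply(seq_len(nrow(paths)), function(r)
    trajectoryLogProb(model, paths[r, ]), numeric(1))
  rows <- list()
  for (i in seq(0L, Tm)) {
    for (len in seq(0L, min(maxLength, Tm - i))) {
      j <- i + len
      sig <- if (len == 0L) rep(0, nrow(paths)) else
        vapply(seq_len(nrow(paths)), function(r)
          fwd[r] - trajectoryLogProb(model, localReverse(paths[r, ], i, j)),
          numeric(1))
      fin <- is.finite(sig)
      rows[[length(rows) + 1L]] <- data.frame(
        i = i, length = len,
        mean_sigma = if (any(fin)) mean(sig[fin]) else NA_real_,
        var_sigma = if (sum(fin) > 1L) stats::var(sig[fin]) else 0,
        n_finite = sum(fin), n_infinite = sum(!fin))
    }
  }
  do.call(rbind, rows)
}
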