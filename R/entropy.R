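#' Normalized Shannon entropy of a next-state distribution
#'
#' \deqn{H_{normalized} = -\sum_i p_i \log p_i / \log N_t}
#' with the 0 log 0 := 0 convention; \code{Nt = 1} returns 0 by convention
#' (a single-cell layer carries no choice). \code{p} must be normalized
#' within 1e-9. The normalization by the log layer size makes entropies
#' comparable across time steps with different numbers of cells.
#'
#' @param p probability vector over the layer-t states
#' @param Nt number of cells at time step t (>= 1)
#' @return real in [0, 1] whenever \code{Nt >= 2} and \code{length(p) <= Nt}
#' @export
normalizedEntropy <- function(p, Nt) {
  stopifnot(Nt >= 1)
  assertProb(p, what = "p")
  if (Nt == 1L) return(0)
  shannon(p) / log(Nt)
}

#' Stepwise normalized-entropy profile of a model
#'
#' For each temperature, samples \code{nSamples} trajectories from the
#' model; at every step t the model's next-token distribution is restricted
#' to the layer-t tokens, temperature-scaled (p proportional to p^(1/T)) and
#' renormalized; its entropy, normalized by the log number of cells at that
#' layer, is averaged over the samples (optionally grouped by the cell type
#' of the sampled token). The next token is drawn from the same restricted,
#' tempered distribution, so sampling and scoring see one distribution.
#' With \code{mode = "empirical"} the model is ignored and the profile is
#' computed from the empirical per-step token frequencies of a supplied
#' ensemble (model-free use; temperature scaling is applied to the
#' frequency vector).
#'
#' @param model an \linkS4class{ARModel} (ignored for empirical mode)
#' @param vocab the \linkS4class{Vocabulary} (token layers, member counts,
#'   cell types)
#' @param nSamples trajectories sampled per temperature (default 100)
#' @param temperatures numeric vector of temperatures
#' @param seed integer seed
#' @param byCellType also return per-cell-type averages
#' @param mode "model" (default) or "empirical"
#' @param ensemble token ensemble, required for empirical mode
#' @return data.frame with columns step, temperature, H (nats), N (cells at
#'   the layer), H_normalized, n (averaged samples); with
#'   \code{byCellType}, an additional cell_type column (plus pooled rows
#'   with cell_type NA)
#' @export
entropyProfile <- function(model, vocab, nSamples = 100L,
                           temperatures = c(0.1, 0.5, 1.0), seed = 0L,
                           byCellType = FALSE,
                           mode = c("model", "empirical"), ensemble = NULL) {
  mode <- match.arg(mode)
  stopifnot(nSamples >= 1)
  lay <- tokenLayer(vocab)
  Tn <- max(lay) + 1L
  layerTokens <- lapply(seq_len(Tn) - 1L, function(t) which(lay == t))
  cellsPerLayer <- vapply(layerTokens, function(tk)
    sum(lengths(vocab@tokenCells[tk])), integer(1))
  temper <- function(p, temp) {
    w <- ifelse(p > 0, p^(1 / temp), 0)
    if (sum(w) == 0) w <- rep(1, length(p))
    w / sum(w)
  }
  rows <- list()
  if (mode == "empirical") {
    if (is.null(ensemble)) stopf("empirical mode needs an ensemble")
    paths <- as.matrix(ensemble)
    for (temp in temperatures) {
      for (t in seq_len(Tn)) {
        freq <- tabulate(paths[, t], nbins = nTokens(vocab))[layerTokens[[t]]]
        p <- temper(freq / sum(freq), temp)
        H <- shannon(p)
        rows[[length(rows) + 1L]] <- data.frame(
          step = t - 1L, temperature = temp, cell_type = NA_character_,
          H = H, N = cellsPerLayer[t],
          H_normalized = if (cellsPerLayer[t] > 1L) H / log(cellsPerLayer[t]) else 0,
          n = nrow(paths))
      }
    }
    res <- do.call(rbind, rows)
    if (!byCellType) res$cell_type <- NULL
    return(res)
  }
  set.seed(stageSeed(seed, "entropy-profile"))
  V <- vocabSize(model)
  samples <- list()
  for (temp in temperatures) {
    for (s in seq_len(nSamples)) {
      prefix <- integer(0)
      for (t in seq_len(Tn)) {
        d0 <- nextDistribution(model, prefix)
        if (length(d0) < nTokens(vocab))        # model fitted on a token subset
          d0 <- c(d0, rep(0, nTokens(vocab) - length(d0)))
        tk <- layerTokens[[t]]
        pRaw <- d0[tk]
        p <- if (sum(pRaw) > 0) temper(pRaw / sum(pRaw), temp)
             else rep(1 / length(tk), length(tk))
        H <- shannon(p)
        tok <- tk[sample.int(length(tk), 1L, prob = p)]
        samples[[length(samples) + 1L]] <- data.frame(
          step = t - 1L, temperature = temp,
          cell_type = tokenType(vocab)[tok], H = H, N = cellsPerLayer[t],
          H_normalized = if (cellsPerLayer[t] > 1L) H / log(cellsPerLayer[t]) else 0)
        prefix <- c(prefix, tok)
      }
    }
  }
  df <- do.call(rbind, samples)
  agg <- function(d, keys) {
    out <- stats::aggregate(cbind(H, H_normalized) ~ ., data = d[, c(keys, "H", "H_normalized")],
                            FUN = mean)
    cnt <- stats::aggregate(list(n = d$H), by = d[, keys, drop = FALSE], FUN = length)
    merge(merge(out, cnt, by = keys),
          unique(df[, c("step", "N")]), by = "step")
  }
  pooled <- agg(df, c("step", "temperature"))
  if (!byCellType) {
    pooled <- pooled[order(pooled$temperature, pooled$step), ]
    rownames(pooled) <- NULL
    return(pooled)
  }
  pooled$cell_type <- NA_character_
  byType <- agg(df, c("step", "temperature", "cell_type"))
  res <- rbind(pooled[, names(byType)], byType)
  res <- res[order(res$temperature, res$step), ]
  rownames(res) <- NULL
  res
}
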