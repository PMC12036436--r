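## Decoder-only causal transformer in plain R with hand-written
## backpropagation and Adam. Deliberately desk-scale: sequences are short
## (tens of steps) and vocabularies small (tens to hundreds of tokens), so
## dense base-R matrix algebra is sufficient and keeps every gradient
## auditable (the test suite checks them against finite differences).

LN_EPS <- 1e-5

#' Transformer hyperparameters
#'
#' @param nLayersModel decoder blocks (default 2)
#' @param width model width d (default 64)
#' @param nHeads attention heads (must divide width; default 4)
#' @param mlpMult MLP hidden width multiplier (default 4)
#' @param epochs maximal training epochs (default 80)
#' @param learningRate Adam step size (default 5e-3)
#' @param batchSize minibatch size (default 16)
#' @param holdout held-out fraction for the per-epoch evaluation (default 0.2)
#' @param patience early-stopping patience on held-out loss (default 10)
#' @param nGenEval trajectories generated per epoch for the coverage metric
#' @param logCoverage log per-epoch coverage (default TRUE)
#' @return named list of hyperparameters
#' @export
modelConfig <- function(nLayersModel = 2L, width = 64L, nHeads = 4L,
                        mlpMult = 4L, epochs = 80L, learningRate = 5e-3,
                        batchSize = 16L, holdout = 0.2, patience = 10L,
                        nGenEval = 16L, logCoverage = TRUE) {
  if (width %% nHeads != 0L) stopf("width must be divisible by nHeads")
  list(nLayersModel = as.integer(nLayersModel), width = as.integer(width),
       nHeads = as.integer(nHeads), mlpMult = as.integer(mlpMult),
       epochs = as.integer(epochs), learningRate = learningRate,
       batchSize = as.integer(batchSize), holdout = holdout,
       patience = as.integer(patience), nGenEval = as.integer(nGenEval),
       logCoverage = isTRUE(logCoverage))
}

initTransformerParams <- function(cfg, V, nTypes, maxLen) {
  d <- cfg$width; dff <- d * cfg$mlpMult
  rn <- function(nr, nc) matrix(rnorm(nr * nc, 0, 0.02), nr, nc)
  p <- list(Etok = rn(V + 1L, d), Etyp = rn(nTypes + 1L, d), Epos = rn(maxLen, d))
  for (l in seq_len(cfg$nLayersModel)) {
    pre <- sprintf("L%d.", l)
    p[[paste0(pre, "g1")]] <- rep(1, d); p[[paste0(pre, "b1")]] <- rep(0, d)
    p[[paste0(pre, "Wq")]] <- rn(d, d); p[[paste0(pre, "Wk")]] <- rn(d, d)
    p[[paste0(pre, "Wv")]] <- rn(d, d); p[[paste0(pre, "Wo")]] <- rn(d, d)
    p[[paste0(pre, "g2")]] <- rep(1, d); p[[paste0(pre, "b2")]] <- rep(0, d)
    p[[paste0(pre, "W1")]] <- rn(d, dff); p[[paste0(pre, "bb1")]] <- rep(0, dff)
    p[[paste0(pre, "W2")]] <- rn(dff, d); p[[paste0(pre, "bb2")]] <- rep(0, d)
  }
  p$gf <- rep(1, d); p$bf <- rep(0, d)
  p$Wout <- rn(d, V); p$bout <- rep(0, V)
  p
}

lnForward <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  invstd <- 1 / sqrt(rowMeans(Xc^2) + LN_EPS)
  xh <- Xc * invstd
  list(Y = sweep(sweep(xh, 2L, g, "*"), 2L, b, "+"), xh = xh, invstd = invstd)
}

lnBackward <- function(dY, cache, g) {
  dxh <- sweep(dY, 2L, g, "*")
  m1 <- rowMeans(dxh)
  m2 <- rowMeans(dxh * cache$xh)
  list(dX = (dxh - m1 - cache$xh * m2) * cache$invstd,
       dg = colSums(dY * cache$xh), db = colSums(dY))
}

## Forward pass over one sequence of input ids (BOS already prepended).
## Returns probs (S x V) and, if wanted, the cache for backprop.
transformerForward <- function(p, cfg, ids, types, keepCache = FALSE) {
  S <- length(ids); d <- cfg$width; H <- cfg$nHeads; dh <- d %/% H
  X <- p$Etok[ids, , drop = FALSE] + p$Etyp[types, , drop = FALSE] +
    p$Epos[seq_len(S), , drop = FALSE]
  mask <- upper.tri(matrix(0, S, S))
  cache <- list(ids = ids, types = types, X0 = X)
  blocks <- vector("list", cfg$nLayersModel)
  for (l in seq_len(cfg$nLayersModel)) {
    pre <- sprintf("L%d.", l)
    bl <- list(Xin = X)
    ln1 <- lnForward(X, p[[paste0(pre, "g1")]], p[[paste0(pre, "b1")]])
    Q <- ln1$Y %*% p[[paste0(pre, "Wq")]]
    K <- ln1$Y %*% p[[paste0(pre, "Wk")]]
    Vv <- ln1$Y %*% p[[paste0(pre, "Wv")]]
    Conc <- matrix(0, S, d)
    A <- vector("list", H)
    for (h in seq_len(H)) {
      ix <- ((h - 1L) * dh + 1L):(h * dh)
      Sc <- tcrossprod(Q[, ix, drop = FALSE], K[, ix, drop = FALSE]) / sqrt(dh)
      Sc[mask] <- -Inf
      Ah <- t(apply(Sc, 1L, softmax))
      if (S == 1L) Ah <- matrix(Ah, 1L, 1L)
      A[[h]] <- Ah
      Conc[, ix] <- Ah %*% Vv[, ix, drop = FALSE]
    }
    O <- Conc %*% p[[paste0(pre, "Wo")]]
    X2 <- X + O
    ln2 <- lnForward(X2, p[[paste0(pre, "g2")]], p[[paste0(pre, "b2")]])
    Z1 <- sweep(ln2$Y %*% p[[paste0(pre, "W1")]], 2L, p[[paste0(pre, "bb1")]], "+")
    H1 <- pmax(Z1, 0)
    M <- sweep(H1 %*% p[[paste0(pre, "W2")]], 2L, p[[paste0(pre, "bb2")]], "+")
    X <- X2 + M
    if (keepCache)
      blocks[[l]] <- c(bl, list(ln1 = ln1, Q = Q, K = K, Vv = Vv, A = A,
                                Conc = Conc, X2 = X2, ln2 = ln2, Z1 = Z1, H1 = H1))
  }
  lnf <- lnForward(X, p$gf, p$bf)
  logits <- sweep(lnf$Y %*% p$Wout, 2L, p$bout, "+")
  probs <- t(apply(logits, 1L, softmax))
  if (nrow(logits) == 1L) probs <- matrix(probs, 1L)
  if (keepCache) {
    cache$blocks <- blocks; cache$lnf <- lnf; cache$Xf <- lnf$Y
    cache$probs <- probs
  }
  list(probs = probs, cache = if (keepCache) cache else NULL)
}

## Loss (sum of -log p over predicted positions) and gradients for one
## sequence; targets[t] is the token to predict at position t (0 = skip).
transformerGrad <- function(p, cfg, ids, types, targets) {
  fw <- transformerForward(p, cfg, ids, types, keepCache = TRUE)
  cache <- fw$cache
  S <- length(ids); d <- cfg$width; H <- cfg$nHeads; dh <- d %/% H
  probs <- fw$probs
  predPos <- which(targets > 0L)
  loss <- -sum(log(probs[cbind(predPos, targets[predPos])]))
  g <- list()
  dLogits <- probs
  dLogits[cbind(predPos, targets[predPos])] <-
    dLogits[cbind(predPos, targets[predPos])] - 1
  dLogits[setdiff(seq_len(S), predPos), ] <- 0
  g$Wout <- crossprod(cache$Xf, dLogits)
  g$bout <- colSums(dLogits)
  dXf <- tcrossprod(dLogits, p$Wout)
  lb <- lnBackward(dXf, cache$lnf, p$gf)
  g$gf <- lb$dg; g$bf <- lb$db
  dX <- lb$dX
  for (l in rev(seq_len(cfg$nLayersModel))) {
    pre <- sprintf("L%d.", l)
    bl <- cache$blocks[[l]]
    ## MLP branch
    dM <- dX
    g[[paste0(pre, "bb2")]] <- colSums(dM)
    g[[paste0(pre, "W2")]] <- crossprod(bl$H1, dM)
    dH1 <- tcrossprod(dM, p[[paste0(pre, "W2")]])
    dZ1 <- dH1 * (bl$Z1 > 0)
    g[[paste0(pre, "bb1")]] <- colSums(dZ1)
    g[[paste0(pre, "W1")]] <- crossprod(bl$ln2$Y, dZ1)
    dXn2 <- tcrossprod(dZ1, p[[paste0(pre, "W1")]])
    lb2 <- lnBackward(dXn2, bl$ln2, p[[paste0(pre, "g2")]])
    g[[paste0(pre, "g2")]] <- lb2$dg; g[[paste0(pre, "b2")]] <- lb2$db
    dX2 <- dX + lb2$dX
    ## attention branch
    dO <- dX2
    g[[paste0(pre, "Wo")]] <- crossprod(bl$Conc, dO)
    dConc <- tcrossprod(dO, p[[paste0(pre, "Wo")]])
    dQ <- matrix(0, S, d); dK <- matrix(0, S, d); dV <- matrix(0, S, d)
    for (h in seq_len(H)) {
      ix <- ((h - 1L) * dh + 1L):(h * dh)
      Ah <- bl$A[[h]]
      dOh <- dConc[, ix, drop = FALSE]
      dA <- tcrossprod(dOh, bl$Vv[, ix, drop = FALSE])
      dV[, ix] <- crossprod(Ah, dOh)
      dSc <- Ah * (dA - rowSums(dA * Ah))
      dQ[, ix] <- dSc %*% bl$K[, ix, drop = FALSE] / sqrt(dh)
      dK[, ix] <- crossprod(dSc, bl$Q[, ix, drop = FALSE]) / sqrt(dh)
    }
    g[[paste0(pre, "Wq")]] <- crossprod(bl$ln1$Y, dQ)
    g[[paste0(pre, "Wk")]] <- crossprod(bl$ln1$Y, dK)
    g[[paste0(pre, "Wv")]] <- crossprod(bl$ln1$Y, dV)
    dXn1 <- tcrossprod(dQ, p[[paste0(pre, "Wq")]]) +
      tcrossprod(dK, p[[paste0(pre, "Wk")]]) +
      tcrossprod(dV, p[[paste0(pre, "Wv")]])
    lb1 <- lnBackward(dXn1, bl$ln1, p[[paste0(pre, "g1")]])
    g[[paste0(pre, "g1")]] <- lb1$dg; g[[paste0(pre, "b1")]] <- lb1$db
    dX <- dX2 + lb1$dX
  }
  ## embeddings
  g$Etok <- matrix(0, nrow(p$Etok), d)
  g$Etyp <- matrix(0, nrow(p$Etyp), d)
  g$Epos <- matrix(0, nrow(p$Epos), d)
  for (t in seq_len(S)) {
    g$Etok[ids[t], ] <- g$Etok[ids[t], ] + dX[t, ]
    g$Etyp[types[t], ] <- g$Etyp[types[t], ] + dX[t, ]
    g$Epos[t, ] <- g$Epos[t, ] + dX[t, ]
  }
  list(loss = loss, nPred = length(predPos), grads = g)
}

## Internal: ids/types with BOS prepended for a token sequence.
bosSequence <- function(model, tokens) {
  V <- model@vocabSize
  list(ids = c(V + 1L, tokens),
       types = c(max(model@tokenTypeIds) + 1L, model@tokenTypeIds[tokens]))
}

#' @rdname nextDistribution
#' @export
setMethod("nextDistribution", "TransformerARModel", function(model, prefix) {
  s <- bosSequence(model, as.integer(prefix))
  fw <- transformerForward(model@params, model@config, s$ids, s$types)
  fw$probs[nrow(fw$probs), ]
})

#' @rdname stepDistributions
#' @export
setMethod("stepDistributions", "TransformerARModel", function(model, tokens) {
  s <- bosSequence(model, as.integer(tokens))
  fw <- transformerForward(model@params, model@config, s$ids, s$types)
  fw$probs[seq_along(tokens), , drop = FALSE]
})

#' @rdname armodelAccessors
#' @export
setMethod("trainingLog", "TransformerARModel", function(model) model@trainingLog)

setMethod("show", "TransformerARModel", function(object) {
  cfg <- object@config
  cat("TransformerARModel: vocab", object@vocabSize, ",", cfg$nLayersModel,
      "blocks x width", cfg$width, "x", cfg$nHeads, "heads\n")
  if (nrow(object@trainingLog))
    cat("  trained", nrow(object@trainingLog), "epochs; final eval loss",
        signif(utils::tail(object@trainingLog$evalLoss, 1L), 4), "nats/step\n")
})

adamStep <- function(p, g, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t; corr2 <- 1 - beta2^state$t
  for (nm in names(g)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    p[[nm]] <- p[[nm]] - lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(p = p, state = state)
}

#' Train the causal transformer on a tokenized ensemble
#'
#' Minimizes the mean trajectory action (cross-entropy in nats per step) by
#' Adam over minibatches; the input at each position is the sum of token,
#' cell-type and position embeddings, with a learned begin-of-sequence token
#' prepended so the first step has an empty-prefix distribution. Per epoch
#' the training log records the training loss and, on a held-out split,
#' loss, exact-token and layer-order accuracy, and the token coverage of a
#' small generated sample. Early stopping restores the parameters of the
#' best held-out loss. Identical seed and inputs give an identical log.
#'
#' @param ensemble token-kind training \linkS4class{TrajectoryEnsemble}
#' @param vocab the \linkS4class{Vocabulary} (token layers and cell types)
#' @param config hyperparameters from [modelConfig()]
#' @param seed integer seed
#' @return a \linkS4class{TransformerARModel} (training log attached)
#' @export
trainTransformer <- function(ensemble, vocab, config = modelConfig(), seed = 0L) {
  paths <- as.matrix(ensemble)
  V <- nTokens(vocab)
  if (max(paths) > V)
    stopf("ensemble contains token %d but the vocabulary has %d tokens",
          max(paths), V)
  set.seed(stageSeed(seed, "train-transformer"))
  typeLevels <- sort(unique(vocab@tokenType))
  tokenTypeIds <- match(vocab@tokenType, typeLevels)
  L <- ncol(paths); maxLen <- L + 1L
  p <- initTransformerParams(config, V, length(typeLevels), maxLen)

  n <- nrow(paths)
  nEval <- max(1L, round(config$holdout * n))
  perm <- sample.int(n)
  evalIdx <- perm[seq_len(nEval)]
  trainIdx <- perm[-seq_len(nEval)]
  if (!length(trainIdx)) stopf("ensemble too small for the held-out split")
  evalEns <- methods::new("TrajectoryEnsemble",
                          paths = paths[evalIdx, , drop = FALSE],
                          kind = "token", ids = character())

  state <- list(t = 0L, m = lapply(p, function(x) x * 0),
                v = lapply(p, function(x) x * 0))
  mkModel <- function(pp, log) methods::new("TransformerARModel",
    vocabSize = V, seqLength = L, params = pp, config = config,
    tokenTypeIds = as.integer(tokenTypeIds), trainingLog = log)

  seqOf <- function(row) {
    list(ids = c(V + 1L, row),
         types = c(length(typeLevels) + 1L, tokenTypeIds[row]),
         targets = c(row, 0L))
  }
  evalLoss <- function(pp) {
    tot <- 0; np <- 0L
    for (i in seq_along(evalIdx)) {
      s <- seqOf(paths[evalIdx[i], ])
      fw <- transformerForward(pp, config, s$ids, s$types)
      pr <- fw$probs[cbind(seq_len(L), paths[evalIdx[i], ])]
      tot <- tot - sum(log(pr)); np <- np + L
    }
    tot / np
  }

  log <- data.frame()
  best <- list(loss = Inf, p = p, epoch = 0L)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(trainIdx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    epochLoss <- 0; epochPred <- 0L
    for (b in batches) {
      acc <- NULL; nPred <- 0L
      for (i in b) {
        s <- seqOf(paths[i, ])
        gr <- transformerGrad(p, config, s$ids, s$types, s$targets)
        epochLoss <- epochLoss + gr$loss; nPred <- nPred + gr$nPred
        acc <- if (is.null(acc)) gr$grads else Map(`+`, acc, gr$grads)
      }
      epochPred <- epochPred + nPred
      acc <- lapply(acc, function(x) x / nPred)
      st <- adamStep(p, acc, state, config$learningRate)
      p <- st$p; state <- st$state
    }
    el <- evalLoss(p)
    model <- mkModel(p, log)
    accs <- sequenceAccuracy(model, evalEns, vocab)
    cov <- NA_real_
    if (config$logCoverage) {
      gen <- generateTrajectories(model, config$nGenEval, samplerSettings(),
                                  seed = sample.int(2^30, 1L))
      cov <- tokenCoverage(gen$ensemble, evalEns)
    }
    log <- rbind(log, data.frame(epoch = epoch,
                                 trainLoss = epochLoss / epochPred,
                                 evalLoss = el, evalAccuracy = accs$exact,
                                 evalLayerAccuracy = accs$layerOrder,
                                 coverage = cov))
    if (el < best$loss - 1e-6) best <- list(loss = el, p = p, epoch = epoch)
    if (epoch - best$epoch >= config$patience) break
  }
  mkModel(best$p, log)
}
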