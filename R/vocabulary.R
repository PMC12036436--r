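## Per-layer Voronoi tokenization of configuration space.

## Seeded Lloyd iterations with best-of-restarts; empty centroids dropped,
## nearest-centroid ties broken by lowest centroid id (which.min).
lloyd <- function(X, k, nRestarts = 5L, maxIter = 50L) {
  uniq <- unique(X)
  kEff <- min(k, nrow(uniq))
  nearest <- function(C) {
    d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
    apply(d2, 1L, which.min)
  }
  if (kEff >= nrow(uniq))
    return(list(centroids = uniq, assign = nearest(uniq)))
  best <- NULL
  for (r in seq_len(nRestarts)) {
    C <- uniq[sample.int(nrow(uniq), kEff), , drop = FALSE]
    for (it in seq_len(maxIter)) {
      a <- nearest(C)
      keep <- sort(unique(a))
      Cnew <- do.call(rbind, lapply(keep, function(g)
        colMeans(X[a == g, , drop = FALSE])))
      if (length(keep) == nrow(C) && max(abs(Cnew - C)) < 1e-10) { C <- Cnew; break }
      C <- Cnew
    }
    a <- nearest(C)
    wss <- sum((X - C[a, , drop = FALSE])^2)
    if (is.null(best) || wss < best$wss - 1e-12)
      best <- list(centroids = C, assign = a, wss = wss)
  }
  best[c("centroids", "assign")]
}

#' Fit a per-layer Voronoi vocabulary
#'
#' Per time layer, centroid-based vector quantization of the configuration
#' vectors with \code{min(vocabSizePerLayer, N_t)} centroids (the Voronoi
#' partition induced by the fitted centroids): seeded Lloyd iterations with
#' best-of-restarts initialization, cells assigned to the nearest centroid
#' (ties to the lowest token id), empty centroids dropped. Token metadata
#' records each token's layer, majority cell type and member cells.
#'
#' @param configs a \linkS4class{ConfigurationMatrix}
#' @param table the \linkS4class{CellTable} (for cell types)
#' @param vocabSizePerLayer target tokens per layer (>= 1)
#' @param seed integer seed (deterministic assignment)
#' @return a \linkS4class{Vocabulary}
#' @export
fitVocabulary <- function(configs, table, vocabSizePerLayer, seed = 0L) {
  stopifnot(vocabSizePerLayer >= 1)
  set.seed(stageSeed(seed, "tokenize"))
  lay <- configs@layer
  types <- cellTypes(table)
  cent <- list(); tokLayer <- integer(); tokType <- character()
  tokCells <- list()
  cellTok <- integer(length(lay))
  for (t in sort(unique(lay))) {
    cells <- which(lay == t)
    fit <- lloyd(configs@coords[cells, , drop = FALSE], vocabSizePerLayer)
    off <- length(tokLayer)
    for (g in seq_len(nrow(fit$centroids))) {
      members <- cells[fit$assign == g]
      cent[[off + g]] <- fit$centroids[g, ]
      tokLayer[off + g] <- t
      tokCells[[off + g]] <- members
      tokType[off + g] <- names(sort(base::table(types[members]),
                                     decreasing = TRUE))[1L]
      cellTok[members] <- off + g
    }
  }
  methods::new("Vocabulary", centroids = do.call(rbind, cent),
               tokenLayer = tokLayer, tokenType = tokType,
               tokenCells = tokCells, cellToToken = cellTok,
               cellIds = configs@cellIds)
}

#' Accessors for Vocabulary
#'
#' \code{nTokens}: vocabulary size; \code{tokenLayer}/\code{tokenType}:
#' per-token time layer and majority cell type; \code{cellToToken}: integer
#' map cell index -> token id.
#'
#' @param x a \linkS4class{Vocabulary}
#' @name vocabularyAccessors
NULL

#' @rdname vocabularyAccessors
#' @export
setMethod("nTokens", "Vocabulary", function(x) nrow(x@centroids))

#' @rdname vocabularyAccessors
#' @export
setMethod("tokenLayer", "Vocabulary", function(x) x@tokenLayer)

#' @rdname vocabularyAccessors
#' @export
setMethod("tokenType", "Vocabulary", function(x) x@tokenType)

#' @rdname vocabularyAccessors
#' @export
setMethod("cellToToken", "Vocabulary", function(x) x@cellToToken)

setMethod("show", "Vocabulary", function(object) {
  cat("Vocabulary:", nTokens(object), "tokens over",
      length(unique(object@tokenLayer)), "layers\n")
  cat("  tokens per layer:",
      paste(table(object@tokenLayer), collapse = " "), "\n")
})

#' Total within-token sum of squared distances
#' @param vocab a \linkS4class{Vocabulary}
#' @param configs the \linkS4class{ConfigurationMatrix} it was fitted on
#' @return numeric quantization error
#' @export
quantizationError <- function(vocab, configs) {
  sum(vapply(seq_len(nTokens(vocab)), function(tok) {
    m <- configs@coords[vocab@tokenCells[[tok]], , drop = FALSE]
    sum(sweep(m, 2L, vocab@centroids[tok, ])^2)
  }, numeric(1)))
}

#' Encode a cell ensemble into token sequences
#'
#' Maps cell indices to tokens positionally via the vocabulary's
#' cell-to-token map. Unknown cells raise a lookup error.
#'
#' @param ensemble a cell-kind \linkS4class{TrajectoryEnsemble}
#' @param vocab a \linkS4class{Vocabulary}
#' @return a token-kind \linkS4class{TrajectoryEnsemble}
#' @export
encodeTrajectories <- function(ensemble, vocab) {
  if (trajectoryKind(ensemble) != "cell")
    stopf("encodeTrajectories expects a cell-kind ensemble")
  idx <- as.matrix(ensemble)
  if (any(idx < 1L) || any(idx > length(vocab@cellToToken)))
    stopf("unknown cell index in ensemble")
  toks <- matrix(vocab@cellToToken[idx], nrow = nrow(idx))
  methods::new("TrajectoryEnsemble", paths = toks, kind = "token",
               ids = character())
}

#' Decode a token sequence to its centroid vectors
#'
#' Validates that the token at position t belongs to layer t-1 before
#' returning the per-step centroid matrix.
#'
#' @param tokens integer token vector
#' @param vocab a \linkS4class{Vocabulary}
#' @return numeric matrix, one centroid row per position
#' @export
decodeTokens <- function(tokens, vocab) {
  if (any(tokens < 1L) || any(tokens > nTokens(vocab)))
    stopf("unknown token id")
  wrong <- which(vocab@tokenLayer[tokens] != seq_along(tokens) - 1L)
  if (length(wrong))
    stopf("token at position %d belongs to layer %d, expected layer %d",
          wrong[1L], vocab@tokenLayer[tokens[wrong[1L]]], wrong[1L] - 1L)
  vocab@centroids[tokens, , drop = FALSE]
}
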