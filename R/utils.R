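## Internal helpers: seeding, argument checks, small numerics.

#' Derive a named RNG substream seed from a master seed
#'
#' Every stochastic stage of a run draws its own stream from the master seed
#' and its stage name, so stages can be re-run in isolation and still be
#' reproducible end to end. Deterministic, stays below 2^31.
#'
#' @param seed non-negative integer master seed
#' @param stage character stage name (e.g. "simulate", "tokenize")
#' @return an integer seed
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  h <- 0
  for (ch in utf8ToInt(as.character(stage)))
    h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

withSeed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assertProb <- function(p, tol = 1e-9, what = "p") {
  if (any(p < -tol)) stopf("%s has negative entries", what)
  if (abs(sum(p) - 1) > tol) stopf("%s is not normalized (sums to %.12g)", what, sum(p))
  invisible(TRUE)
}

## Shannon entropy in nats with the 0 log 0 := 0 convention.
shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

## Pearson correlation with the constant-vector convention corr := 0.
corrOrZero <- function(x, y, warn = TRUE) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    if (warn) warning("constant configuration vector; correlation set to 0", call. = FALSE)
    return(0)
  }
  stats::cor(x, y)
}

## Row-wise Pearson correlation of one vector against rows of a matrix.
corrVecRows <- function(v, m, warn = TRUE) {
  vapply(seq_len(nrow(m)), function(i) corrOrZero(v, m[i, ], warn = warn), numeric(1))
}

## Numerically stable softmax.
softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
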