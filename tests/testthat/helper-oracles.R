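## Independent brute-force oracles used across the suite.

## Balanced Forman curvature by exhaustive enumeration over node tuples:
## triangles, diagonal-free 4-cycles i-k-w-j, and gamma_max, all counted by
## a plain double loop over ordered pairs (k, w). Deliberately naive.
oracleBalancedForman <- function(A, i, j) {
  stopifnot(A[i, j] == 1)
  n <- nrow(A)
  d <- rowSums(A)
  if (min(d[i], d[j]) == 1) return(0)
  tri <- 0
  for (k in seq_len(n)) if (k != i && k != j && A[i, k] && A[j, k]) tri <- tri + 1
  ks <- integer(0); ws <- integer(0)
  hits <- integer(n)                        # cycles traversing each node
  for (k in seq_len(n)) for (w in seq_len(n)) {
    if (k %in% c(i, j) || w %in% c(i, j) || k == w) next
    if (A[i, k] && A[k, w] && A[w, j] && !A[k, j] && !A[w, i]) {
      ks <- c(ks, k); ws <- c(ws, w)
      hits[k] <- hits[k] + 1L; hits[w] <- hits[w] + 1L
    }
  }
  Si <- length(unique(ks)); Sj <- length(unique(ws))
  gmax <- if (length(ks)) max(hits) else 0
  ric <- 2 / d[i] + 2 / d[j] - 2 + 2 * tri / max(d[i], d[j]) +
    tri / min(d[i], d[j])
  if (gmax > 0) ric <- ric + (Si + Sj) / (gmax * max(d[i], d[j]))
  ric
}

## Seeded Erdos-Renyi adjacency matrix (symmetric, no self loops).
randomAdjacency <- function(n, p) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(stats::runif(length(up)) < p)
  A + t(A)
}

## Adjacency matrices of named small graphs.
pathGraph3 <- function() {
  A <- matrix(0L, 3, 3); A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1L
  A
}
cycleGraph4 <- function() {
  A <- matrix(0L, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))) A[e[1], e[2]] <- A[e[2], e[1]] <- 1L
  A
}
completeGraph4 <- function() {
  A <- matrix(1L, 4, 4); diag(A) <- 0L
  A
}
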