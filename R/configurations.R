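#' Build per-cell configuration vectors
#'
#' Expression is standardized gene-wise over all cells pooled (zero mean,
#' unit variance; zero-variance genes are dropped with a warning) and
#' projected onto its top \code{nPcs} principal axes. Velocity is scaled by
#' the same per-gene standard deviations (a velocity transforms like the
#' derivative of the standardized expression), projected onto the *same*
#' basis, multiplied by \code{velocityWeight}, and concatenated, giving the
#' generalized coordinate C = (x, velocityWeight * xdot) per cell. With
#' \code{velocityWeight = 0} the configuration is the projected expression
#' alone (dimension \code{nPcs}); otherwise dimension \code{2 * nPcs}.
#'
#' @param table a \linkS4class{CellTable}
#' @param nPcs number of principal axes (<= min(n cells, n kept genes))
#' @param velocityWeight non-negative weight of the velocity block
#' @return a \linkS4class{ConfigurationMatrix}
#' @export
buildConfigurations <- function(table, nPcs = 30L, velocityWeight = 1) {
  expr <- t(expressionMatrix(table))          # cells x genes
  vel <- t(velocityMatrix(table))
  mu <- colMeans(expr)
  sdv <- apply(expr, 2L, stats::sd)
  keep <- sdv > 0
  dropped <- colnames(expr)[!keep]
  if (length(dropped))
    warning(sprintf("dropping %d zero-variance gene(s)", length(dropped)),
            call. = FALSE)
  expr <- expr[, keep, drop = FALSE]
  vel <- vel[, keep, drop = FALSE]
  mu <- mu[keep]; sdv <- sdv[keep]
  nPcs <- as.integer(nPcs)
  if (nPcs > min(nrow(expr), ncol(expr)))
    stopf("nPcs = %d exceeds min(n cells = %d, n genes kept = %d)",
          nPcs, nrow(expr), ncol(expr))
  z <- sweep(sweep(expr, 2L, mu), 2L, sdv, "/")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  basis <- pc$rotation[, seq_len(nPcs), drop = FALSE]
  xs <- z %*% basis
  coords <- if (velocityWeight > 0) {
    vz <- sweep(vel, 2L, sdv, "/")
    cbind(xs, velocityWeight * (vz %*% basis))
  } else xs
  rownames(coords) <- cellIds(table)
  methods::new("ConfigurationMatrix", coords = coords,
               layer = timeSteps(table), cellIds = cellIds(table),
               basis = basis, geneMeans = mu, geneSds = sdv,
               droppedGenes = as.character(dropped), nPcs = nPcs,
               velocityWeight = velocityWeight)
}
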