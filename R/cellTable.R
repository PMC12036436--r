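#' Construct a CellTable from matrices and metadata
#'
#' @param expression numeric expression matrix, cells x genes by default
#'   (see \code{cellsInRows})
#' @param velocity matrix of the same shape as \code{expression}
#' @param metadata data.frame with one row per cell and columns
#'   \code{cell_id}, \code{time}, \code{cell_type}; \code{time} may carry
#'   arbitrary sortable labels, which are rank-mapped to the contiguous range
#'   0..T (the mapping is stored in \code{metadata(x)$timeMap}).
#' @param cellsInRows logical; TRUE (default) when the input matrices are
#'   cells x genes (the common on-disk orientation). Internally the table is
#'   genes x cells.
#' @return a \linkS4class{CellTable}
#' @export
makeCellTable <- function(expression, velocity, metadata, cellsInRows = TRUE) {
  expression <- as.matrix(expression)
  velocity <- as.matrix(velocity)
  if (!identical(dim(expression), dim(velocity)))
    stopf("expression (%d x %d) and velocity (%d x %d) must have identical shape",
          nrow(expression), ncol(expression), nrow(velocity), ncol(velocity))
  need <- c("cell_id", "time", "cell_type")
  miss <- setdiff(need, colnames(metadata))
  if (length(miss))
    stopf("metadata lacks column(s): %s", paste(miss, collapse = ", "))
  if (cellsInRows) {
    expression <- t(expression)
    velocity <- t(velocity)
  }
  if (ncol(expression) != nrow(metadata))
    stopf("metadata has %d rows but there are %d cells", nrow(metadata), ncol(expression))

  rawTime <- metadata$time
  lev <- sort(unique(rawTime))
  mapped <- match(rawTime, lev) - 1L
  ## Numeric labels must already be contiguous from 0: a silent rank-map of,
  ## say, {0, 2} would hide a missing step.
  if (is.numeric(rawTime)) {
    tm <- sort(unique(as.integer(rawTime)))
    if (!identical(tm, seq(0L, max(tm)))) {
      gaps <- setdiff(seq(0L, max(tm)), tm)
      stopf("time labels are numeric but not contiguous from 0 (missing %s)",
            paste(gaps, collapse = ", "))
    }
    mapped <- as.integer(rawTime)
  }
  cd <- S4Vectors::DataFrame(
    cell_id = as.character(metadata$cell_id),
    time = mapped,
    cell_type = as.character(metadata$cell_type)
  )
  colnames(expression) <- colnames(velocity) <- cd$cell_id
  if (is.null(rownames(expression)))
    rownames(expression) <- rownames(velocity) <- paste0("g", seq_len(nrow(expression)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expression = expression, velocity = velocity), colData = cd)
  obj <- methods::new("CellTable", se)
  S4Vectors::metadata(obj)$timeMap <- data.frame(label = as.character(lev),
                                                step = seq_along(lev) - 1L)
  obj
}

#' Accessors for CellTable
#'
#' \code{expressionMatrix}/\code{velocityMatrix} return the genes x cells
#' assays; \code{timeSteps} the 0-based time step per cell; \code{cellTypes}
#' and \code{cellIds} per-cell labels; \code{layerSizes} a named vector of
#' cells per time layer; \code{nLayers} the number of layers T+1.
#'
#' @param x a \linkS4class{CellTable}
#' @name cellTableAccessors
NULL

#' @rdname cellTableAccessors
#' @export
setMethod("expressionMatrix", "CellTable", function(x)
  SummarizedExperiment::assay(x, "expression"))

#' @rdname cellTableAccessors
#' @export
setMethod("velocityMatrix", "CellTable", function(x)
  SummarizedExperiment::assay(x, "velocity"))

#' @rdname cellTableAccessors
#' @export
setMethod("timeSteps", "CellTable", function(x)
  as.integer(SummarizedExperiment::colData(x)$time))

#' @rdname cellTableAccessors
#' @export
setMethod("cellTypes", "CellTable", function(x)
  as.character(SummarizedExperiment::colData(x)$cell_type))

#' @rdname cellTableAccessors
#' @export
setMethod("cellIds", "CellTable", function(x)
  as.character(SummarizedExperiment::colData(x)$cell_id))

#' @rdname cellTableAccessors
#' @export
setMethod("layerSizes", "CellTable", function(x) {
  tt <- timeSteps(x)
  tab <- table(factor(tt, levels = seq(0L, max(tt))))
  stats::setNames(as.integer(tab), names(tab))
})

#' @rdname cellTableAccessors
#' @export
setMethod("nLayers", "CellTable", function(x) max(timeSteps(x)) + 1L)

## Cell indices (columns) of one time layer, in column order.
layerCells <- function(table, t) which(timeSteps(table) == t)

setMethod("show", "CellTable", function(object) {
  cat("CellTable:", ncol(object), "cells x", nrow(object), "genes,",
      nLayers(object), "time layers\n")
  cat("  layer sizes:", paste(layerSizes(object), collapse = " "), "\n")
  cat("  cell types:", paste(unique(cellTypes(object)), collapse = ", "), "\n")
})
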