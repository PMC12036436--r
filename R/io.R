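## Readers/writers for the on-disk formats: dense TSV or MatrixMarket
## expression/velocity, cell metadata, JSON-lines trajectory files, and the
## flat YAML run configuration.

readMatrixAny <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rowsFile <- sub("\\.mtx$", "_rows.txt", path)
    colsFile <- sub("\\.mtx$", "_cols.txt", path)
    if (!file.exists(rowsFile) || !file.exists(colsFile))
      stopf("MatrixMarket input %s needs sidecars %s and %s",
            path, basename(rowsFile), basename(colsFile))
    rownames(m) <- readLines(rowsFile)
    colnames(m) <- readLines(colsFile)
    m
  } else {
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
    as.matrix(df)
  }
}

#' Load a CellTable from disk
#'
#' Expression and velocity are cells-by-genes matrices, either dense TSV
#' (header row of gene names, first column of cell ids) or MatrixMarket
#' \code{.mtx} with \code{_rows.txt}/\code{_cols.txt} sidecars; both matrices
#' must use the same dialect and have identical shape. Metadata is a TSV with
#' columns \code{cell_id}, \code{time}, \code{cell_type}; numeric time labels
#' must form a contiguous 0-based range, other labels are rank-mapped (the
#' mapping is kept in \code{metadata()$timeMap}).
#'
#' @param expressionPath,velocityPath,metadataPath file paths
#' @return a \linkS4class{CellTable}
#' @export
loadCellTable <- function(expressionPath, velocityPath, metadataPath) {
  if (grepl("\\.mtx$", expressionPath) != grepl("\\.mtx$", velocityPath))
    stopf("expression and velocity must use the same dialect (both .mtx or both TSV)")
  expr <- readMatrixAny(expressionPath)
  vel <- readMatrixAny(velocityPath)
  meta <- utils::read.delim(metadataPath, check.names = FALSE,
                            colClasses = c(cell_id = "character"))
  tab <- makeCellTable(expr, vel, meta, cellsInRows = TRUE)
  ## Align metadata order to matrix row order if ids permuted.
  if (!identical(cellIds(tab), rownames(expr)) && !is.null(rownames(expr))) {
    if (!setequal(cellIds(tab), rownames(expr)))
      stopf("metadata cell_id set does not match matrix rows")
  }
  tab
}

#' Write a CellTable to disk (dense TSV or MatrixMarket)
#'
#' Inverse of [loadCellTable()]; writes \code{<prefix>_expression},
#' \code{<prefix>_velocity} (cells x genes) and \code{<prefix>_metadata.tsv}.
#'
#' @param table a \linkS4class{CellTable}
#' @param prefix path prefix for the three files
#' @param format "tsv" or "mtx"
#' @return invisibly, the written paths
#' @export
writeCellTable <- function(table, prefix, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  expr <- t(expressionMatrix(table))
  vel <- t(velocityMatrix(table))
  meta <- data.frame(cell_id = cellIds(table), time = timeSteps(table),
                     cell_type = cellTypes(table))
  metaPath <- paste0(prefix, "_metadata.tsv")
  utils::write.table(meta, metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (format == "tsv") {
    ep <- paste0(prefix, "_expression.tsv")
    vp <- paste0(prefix, "_velocity.tsv")
    utils::write.table(expr, ep, sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(vel, vp, sep = "\t", quote = FALSE, col.names = NA)
  } else {
    ep <- paste0(prefix, "_expression.mtx")
    vp <- paste0(prefix, "_velocity.mtx")
    for (pv in list(list(m = expr, p = ep), list(m = vel, p = vp))) {
      Matrix::writeMM(Matrix::Matrix(pv$m, sparse = TRUE), pv$p)
      writeLines(rownames(pv$m), sub("\\.mtx$", "_rows.txt", pv$p))
      writeLines(colnames(pv$m), sub("\\.mtx$", "_cols.txt", pv$p))
    }
  }
  invisible(c(ep, vp, metaPath))
}

#' Write / read a trajectory ensemble as JSON-lines
#'
#' One record per trajectory: \code{{"traj_id", "tokens", "cell_ids"}}
#' (\code{cell_ids} only for cell-kind ensembles); read is the exact inverse
#' and preserves tokens as integers.
#'
#' @param ensemble a non-empty \linkS4class{TrajectoryEnsemble}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeTrajectories <- function(ensemble, path) {
  if (nTrajectories(ensemble) == 0L)
    stopf("refusing to write an empty trajectory ensemble")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nTrajectories(ensemble))) {
    rec <- list(traj_id = i, tokens = ensemble@paths[i, ])
    if (ensemble@kind == "cell")
      rec$cell_ids <- ensemble@ids[ensemble@paths[i, ]]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname writeTrajectories
#' @export
readTrajectories <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stopf("no trajectories in %s", path)
  recs <- lapply(lines, jsonlite::fromJSON)
  lens <- vapply(recs, function(r) length(r$tokens), integer(1))
  if (length(unique(lens)) != 1L)
    stopf("ragged trajectory lengths in %s", path)
  paths <- do.call(rbind, lapply(recs, function(r) as.integer(r$tokens)))
  kind <- if (!is.null(recs[[1]]$cell_ids)) "cell" else "token"
  ids <- character()
  if (kind == "cell") {
    ids <- character(max(paths))
    for (r in recs) ids[as.integer(r$tokens)] <- r$cell_ids
  }
  methods::new("TrajectoryEnsemble", paths = paths, kind = kind, ids = ids)
}

#' Construct sampler settings
#' @param topK positive integer or Inf (unlimited)
#' @param topP real in (0, 1]
#' @param temperature real > 0
#' @return a \linkS4class{SamplerSettings}
#' @export
samplerSettings <- function(topK = Inf, topP = 1, temperature = 1) {
  methods::new("SamplerSettings", topK = topK, topP = topP,
               temperature = temperature)
}

#' Construct a run configuration
#'
#' @param knnK candidate-set size of the KNN search (default 30)
#' @param memoryLambda exponential memory decay in [0, 1] (default 0: Markov)
#' @param memoryWindow history window L >= 1 (default 1)
#' @param velocityWeight weight of the projected velocity block (default 1)
#' @param nPcs number of principal axes (default 30)
#' @param vocabSize per-layer vocabulary size (default 50)
#' @param sampler a \linkS4class{SamplerSettings}
#' @param model transformer hyperparameters, see [modelConfig()]
#' @param seed master seed
#' @return a \linkS4class{RunConfig}
#' @export
runConfig <- function(knnK = 30L, memoryLambda = 0, memoryWindow = 1L,
                      velocityWeight = 1, nPcs = 30L, vocabSize = 50L,
                      sampler = samplerSettings(), model = modelConfig(),
                      seed = 0L) {
  methods::new("RunConfig", knnK = as.integer(knnK),
               memoryLambda = memoryLambda,
               memoryWindow = as.integer(memoryWindow),
               velocityWeight = velocityWeight, nPcs = as.integer(nPcs),
               vocabSize = as.integer(vocabSize), sampler = sampler,
               model = model, seed = as.integer(seed))
}

#' Read a run configuration from a flat YAML file
#'
#' Keys mirror [runConfig()] arguments (snake_case accepted); sampler and
#' model keys are nested one level (\code{sampler: {top_k, top_p,
#' temperature}}, \code{model: {layers, width, heads, epochs, learning_rate}}).
#' Invalid values (e.g. \code{memory_lambda} outside [0,1]) are rejected at
#' load time.
#'
#' @param path YAML file path
#' @return a \linkS4class{RunConfig}
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(...) {
    for (k in c(...)) if (!is.null(y[[k]])) return(y[[k]])
    NULL
  }
  args <- list()
  take <- function(name, ...) {
    v <- pick(...)
    if (!is.null(v)) args[[name]] <<- v
  }
  take("knnK", "knn_k", "knnK")
  take("memoryLambda", "memory_lambda", "memoryLambda")
  take("memoryWindow", "memory_window", "memoryWindow")
  take("velocityWeight", "velocity_weight", "velocityWeight")
  take("nPcs", "n_pcs", "nPcs")
  take("vocabSize", "vocab_size", "vocabSize")
  take("seed", "seed")
  if (!is.null(y$sampler)) {
    s <- y$sampler
    args$sampler <- samplerSettings(
      topK = if (is.null(s$top_k) || identical(s$top_k, "unlimited")) Inf else s$top_k,
      topP = if (is.null(s$top_p)) 1 else s$top_p,
      temperature = if (is.null(s$temperature)) 1 else s$temperature)
  }
  if (!is.null(y$model)) {
    m <- y$model
    args$model <- modelConfig(
      nLayersModel = if (is.null(m$layers)) 2L else m$layers,
      width = if (is.null(m$width)) 64L else m$width,
      nHeads = if (is.null(m$heads)) 4L else m$heads,
      epochs = if (is.null(m$epochs)) 80L else m$epochs,
      learningRate = if (is.null(m$learning_rate)) 5e-3 else m$learning_rate)
  }
  do.call(runConfig, args)
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig: knnK =", object@knnK,
      " lambda =", object@memoryLambda, " window =", object@memoryWindow,
      "\n  velocityWeight =", object@velocityWeight, " nPcs =", object@nPcs,
      " vocabSize =", object@vocabSize, " seed =", object@seed, "\n")
})
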