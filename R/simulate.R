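#' Specify a branching synthetic lineage
#'
#' @param nLayers number of time layers T+1 (>= 2)
#' @param cellsPerLayer cells sampled at every layer
#' @param nGenes genes per cell
#' @param branchPoints list of branch points, each
#'   \code{list(layer =, nBranches =, probs =)}; every lineage active at
#'   \code{layer} splits into \code{nBranches} daughters and cells pick a
#'   daughter with probabilities \code{probs}. Branch layers must be
#'   interior (1 <= layer <= T-1).
#' @param bottleneck optional \code{list(layer =, survivingFraction =)}: at
#'   \code{layer}, all but a fraction of lineages have their latent means
#'   collapsed onto the cross-lineage average, shrinking state diversity
#'   there (a developmental bottleneck).
#' @param noiseSd sd of the additive Gaussian expression/velocity noise
#' @param driftScale per-step scale of the latent Gaussian random walk
#' @return a \linkS4class{LineageSpec}
#' @export
lineageSpec <- function(nLayers, cellsPerLayer, nGenes, branchPoints = list(),
                        bottleneck = NULL, noiseSd = 0.2, driftScale = 1) {
  methods::new("LineageSpec", nLayers = as.integer(nLayers),
               cellsPerLayer = as.integer(cellsPerLayer),
               nGenes = as.integer(nGenes), branchPoints = branchPoints,
               bottleneck = if (is.null(bottleneck)) list() else bottleneck,
               noiseSd = noiseSd, driftScale = driftScale)
}

setMethod("show", "LineageSpec", function(object) {
  cat("LineageSpec:", object@nLayers, "layers x", object@cellsPerLayer,
      "cells,", object@nGenes, "genes;", length(object@branchPoints),
      "branch point(s)",
      if (length(object@bottleneck)) sprintf(", bottleneck at layer %d",
                                             object@bottleneck$layer) else "",
      "\n")
})

#' Simulate a branching developmental process with known ground truth
#'
#' Latent lineage means follow a seeded Gaussian random walk per gene
#' (step sd \code{driftScale}); at a branch point each daughter copies the
#' parent mean at the branch layer and then drifts independently. Each cell
#' is assigned a parent drawn uniformly from the previous layer (inheriting
#' its lineage, or choosing a daughter lineage at a branch layer with the
#' designed probabilities); its expression is the lineage mean plus Gaussian
#' noise, and its velocity is the expected displacement to the next-layer
#' lineage mean (probability-weighted over daughters at a branch layer) plus
#' noise, so velocity points along the true lineage direction. A bottleneck
#' collapses the latent means of the non-surviving lineages at its layer
#' onto the cross-lineage average (the first \code{ceil(f * nLineages)}
#' lineages in label order survive).
#'
#' @param spec a \linkS4class{LineageSpec}
#' @param seed integer seed; identical spec + seed give identical output
#' @return \code{list(table = CellTable, truth = SyntheticTruth)}
#' @export
simulateBranchingProcess <- function(spec, seed = 0L) {
  stopifnot(methods::validObject(spec))
  set.seed(stageSeed(seed, "simulate"))
  T1 <- spec@nLayers
  G <- spec@nGenes
  bpAt <- stats::setNames(spec@branchPoints,
                          vapply(spec@branchPoints, function(b) as.character(b$layer), ""))

  ## --- latent lineage tree of mean-expression walks ------------------------
  ## Each lineage is active over a layer interval [from, T1-1]; its mean path
  ## is stored for the full range, copying the parent up to the split.
  lineages <- list(root = list(from = 0L, parent = NA_character_,
                               means = matrix(NA_real_, T1, G)))
  lineages$root$means[1L, ] <- rnorm(G, 0, spec@driftScale)
  active <- "root"
  children <- list()
  for (t in seq_len(T1 - 1L)) {          # filling layer t (0-based)
    bp <- bpAt[[as.character(t)]]
    if (!is.null(bp)) {
      newActive <- character()
      for (lin in active) {
        kids <- paste0(lin, ".", seq_len(bp$nBranches))
        children[[lin]] <- list(labels = kids, probs = bp$probs, layer = t)
        for (kid in kids) {
          lineages[[kid]] <- list(from = t, parent = lin,
                                  means = lineages[[lin]]$means)
        }
        newActive <- c(newActive, kids)
      }
      active <- newActive
    }
    for (lin in active) {
      m <- lineages[[lin]]$means
      m[t + 1L, ] <- m[t, ] + rnorm(G, 0, spec@driftScale)
      lineages[[lin]]$means <- m
    }
  }

  ## Lineage active at a given layer for a lineage label (walk up if needed).
  lineageAt <- function(lin, t) {
    while (lineages[[lin]]$from > t) lin <- lineages[[lin]]$parent
    lin
  }

  ## --- bottleneck: collapse non-surviving lineage means at one layer -------
  collapsed <- character()
  if (length(spec@bottleneck)) {
    bt <- spec@bottleneck$layer
    if (bt >= T1) stopf("bottleneck layer %d is beyond the last layer %d", bt, T1 - 1L)
    linsAtB <- unique(vapply(active, function(l) lineageAt(l, bt), ""))
    nSurv <- max(1L, ceiling(spec@bottleneck$survivingFraction * length(linsAtB)))
    linsAtB <- sort(linsAtB)
    collapsed <- linsAtB[seq_along(linsAtB) > nSurv]
    if (length(collapsed)) {
      centre <- colMeans(do.call(rbind, lapply(linsAtB, function(l)
        lineages[[l]]$means[bt + 1L, ])))
      for (l in collapsed) lineages[[l]]$means[bt + 1L, ] <- centre
    }
  }

  ## --- sample cells layer by layer ------------------------------------------
  n <- spec@cellsPerLayer
  cellLin <- character(T1 * n)
  parentIdx <- rep(NA_integer_, T1 * n)
  idx <- function(t, i) t * n + i               # 1-based within layer
  for (i in seq_len(n)) cellLin[idx(0L, i)] <- "root"
  for (t in seq_len(T1 - 1L)) {
    bp <- bpAt[[as.character(t)]]
    for (i in seq_len(n)) {
      p <- sample.int(n, 1L)
      parentLin <- cellLin[idx(t - 1L, p)]
      lin <- if (!is.null(bp)) {
        kids <- children[[parentLin]]
        cellLin[idx(t, i)] <- kids$labels[sample.int(length(kids$labels), 1L,
                                                     prob = kids$probs)]
        cellLin[idx(t, i)]
      } else {
        cellLin[idx(t, i)] <- lineageAt(parentLin, t)
      }
      parentIdx[idx(t, i)] <- idx(t - 1L, p)
    }
  }

  ## --- expression, velocity, metadata --------------------------------------
  nCells <- T1 * n
  expr <- matrix(0, nCells, G)
  vel <- matrix(0, nCells, G)
  layer <- rep(seq(0L, T1 - 1L), each = n)
  for (c in seq_len(nCells)) {
    t <- layer[c]
    lin <- cellLin[c]
    mu <- lineages[[lin]]$means[t + 1L, ]
    expr[c, ] <- mu + rnorm(G, 0, spec@noiseSd)
    drift <- if (t < T1 - 1L) {
      kids <- children[[lin]]
      if (!is.null(kids) && kids$layer == t + 1L) {
        target <- Reduce(`+`, Map(function(k, p) p * lineages[[k]]$means[t + 2L, ],
                                  kids$labels, kids$probs))
        target - mu
      } else lineages[[lineageAt(lin, t + 1L)]]$means[t + 2L, ] - mu
    } else {
      mu - lineages[[lin]]$means[t, ]          # terminal layer: keep heading
    }
    vel[c, ] <- drift + rnorm(G, 0, spec@noiseSd)
  }
  ids <- sprintf("cell_%04d", seq_len(nCells))
  meta <- data.frame(cell_id = ids, time = layer, cell_type = cellLin)
  table <- makeCellTable(expr, vel, meta, cellsInRows = TRUE)

  truth <- methods::new("SyntheticTruth",
    cells = data.frame(cell_id = ids, layer = layer, lineage = cellLin,
                       parent_cell_id = ifelse(is.na(parentIdx), NA, ids[parentIdx])),
    branchPoints = spec@branchPoints,
    bottleneck = spec@bottleneck,
    branchMeans = lapply(lineages, `[[`, "means"),
    children = children)
  list(table = table, truth = truth)
}

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@cells), "cells,",
      length(object@branchMeans), "lineage(s)\n")
})

#' Lineage-consistency of a step in the designed tree
#'
#' TRUE when moving from \code{linFrom} (layer t) to \code{linTo} (layer t+1)
#' follows the lineage tree: same lineage, or a daughter created at layer
#' t+1. Used for parameter-recovery checks of sampled trajectories.
#'
#' @param truth a \linkS4class{SyntheticTruth}
#' @param linFrom,linTo lineage labels
#' @param toLayer the (0-based) layer of \code{linTo}
#' @return logical
#' @export
followsLineage <- function(truth, linFrom, linTo, toLayer) {
  if (identical(linFrom, linTo)) return(TRUE)
  kids <- truth@children[[linFrom]]
  !is.null(kids) && kids$layer == toLayer && linTo %in% kids$labels
}
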