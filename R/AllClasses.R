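#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor prcomp rnorm runif sd var setNames aggregate
#' @importFrom utils head tail read.delim write.table
NULL

#' CellTable: time-stamped cells with expression and velocity
#'
#' A \linkS4class{SummarizedExperiment} holding two equally shaped assays,
#' \code{"expression"} and \code{"velocity"}, with genes in rows and cells in
#' columns. \code{colData} carries one row per cell with the columns
#' \code{cell_id}, \code{time} (a contiguous 0-based integer time step) and
#' \code{cell_type}. The pair (expression, velocity) of a cell is its
#' generalized coordinate in configuration space; grouping cells by
#' \code{time} yields the layered structure every downstream stage
#' (transition kernels, tokenization, trajectory graphs) operates on.
#'
#' @seealso [makeCellTable()], [loadCellTable()], [simulateBranchingProcess()]
#' @export
setClass("CellTable", contains = "SummarizedExperiment")

setValidity("CellTable", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("expression", "velocity") %in% an))
    msg <- c(msg, "assays must include 'expression' and 'velocity'")
  cd <- SummarizedExperiment::colData(object)
  need <- c("cell_id", "time", "cell_type")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (!length(msg)) {
    tm <- sort(unique(as.integer(cd$time)))
    if (length(tm) && !identical(tm, seq(0L, max(tm))))
      msg <- c(msg, paste0("time steps must form a contiguous 0-based range; gap after ",
                           paste(setdiff(seq(0L, max(tm)), tm) - 1L, collapse = ",")))
    if (anyDuplicated(cd$cell_id))
      msg <- c(msg, "cell_id values must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Branching lineage specification for the synthetic-data generator
#'
#' Describes a layered developmental process: \code{nLayers} time layers of
#' \code{cellsPerLayer} cells over \code{nGenes} genes; latent branch means
#' follow a seeded Gaussian random walk with per-step scale \code{driftScale};
#' at each branch point (a list with elements \code{layer}, \code{nBranches},
#' \code{probs}) every active lineage splits, and daughter cells choose a
#' branch with the given probabilities. An optional \code{bottleneck}
#' (\code{layer}, \code{survivingFraction}) collapses the latent means of the
#' non-surviving lineages at that layer onto their common average, shrinking
#' state diversity there. Cells are the branch mean plus Gaussian noise with
#' standard deviation \code{noiseSd}.
#'
#' @seealso [lineageSpec()], [simulateBranchingProcess()]
#' @export
setClass("LineageSpec", representation(
  nLayers       = "integer",
  cellsPerLayer = "integer",
  nGenes        = "integer",
  branchPoints  = "list",
  bottleneck    = "list",
  noiseSd       = "numeric",
  driftScale    = "numeric"
))

setValidity("LineageSpec", function(object) {
  msg <- character()
  if (object@nLayers < 2L) msg <- c(msg, "nLayers must be >= 2")
  if (object@cellsPerLayer < 1L) msg <- c(msg, "cellsPerLayer must be >= 1")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  for (bp in object@branchPoints) {
    if (!all(c("layer", "nBranches", "probs") %in% names(bp)))
      msg <- c(msg, "each branch point needs layer, nBranches, probs")
    else {
      if (bp$layer >= object@nLayers - 1L)
        msg <- c(msg, sprintf("branch point at layer %d but last layer is %d",
                              bp$layer, object@nLayers - 1L))
      if (bp$layer < 1L) msg <- c(msg, "branch point layer must be >= 1")
      if (length(bp$probs) != bp$nBranches)
        msg <- c(msg, "branch probs length must equal nBranches")
      if (abs(sum(bp$probs) - 1) > 1e-8)
        msg <- c(msg, "branch probabilities must sum to 1")
    }
  }
  if (length(object@bottleneck)) {
    bn <- object@bottleneck
    if (!all(c("layer", "survivingFraction") %in% names(bn)))
      msg <- c(msg, "bottleneck needs layer and survivingFraction")
    else if (bn$survivingFraction <= 0 || bn$survivingFraction > 1)
      msg <- c(msg, "bottleneck survivingFraction must be in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated branching process
#'
#' Per-cell lineage labels and parent assignments plus the designed branch
#' probabilities and bottleneck location, for parameter-recovery tests.
#' \code{cells} is a data.frame with columns \code{cell_id}, \code{layer},
#' \code{lineage}, \code{parent_cell_id} (NA for layer-0 cells);
#' \code{branchMeans} maps lineage label to its latent mean path (layers x
#' genes); \code{children} maps lineage label to daughter labels.
#'
#' @export
setClass("SyntheticTruth", representation(
  cells        = "data.frame",
  branchPoints = "list",
  bottleneck   = "list",
  branchMeans  = "list",
  children     = "list"
))

#' Per-cell configuration vectors in reduced dimension
#'
#' Row i is the configuration of cell i: the gene-standardized expression
#' projected on the top \code{nPcs} principal axes, concatenated (when
#' \code{velocityWeight > 0}) with the velocity projected on the same basis
#' and scaled by \code{velocityWeight}. \code{layer} gives each cell's time
#' step, \code{basis} the gene-by-PC rotation, \code{geneMeans}/\code{geneSds}
#' the standardization applied before projection (zero-variance genes are
#' dropped and recorded in \code{droppedGenes}).
#'
#' @seealso [buildConfigurations()]
#' @export
setClass("ConfigurationMatrix", representation(
  coords         = "matrix",
  layer          = "integer",
  cellIds        = "character",
  basis          = "matrix",
  geneMeans      = "numeric",
  geneSds        = "numeric",
  droppedGenes   = "character",
  nPcs           = "integer",
  velocityWeight = "numeric"
))

#' Per-time-step candidate transition kernel
#'
#' For every time step t < T, the k-nearest-neighbor candidate sets (layer-t
#' cell -> k nearest layer-(t+1) cells in configuration space) and the
#' row-stochastic transition probabilities obtained by a softmax over the
#' Pearson correlations of configuration vectors. \code{candidates[[t]]} and
#' \code{probs[[t]]} are lists indexed by the layer-t cells (global cell
#' indices / probabilities summing to 1).
#'
#' @seealso [markovTransitionProbs()], [sampleTrajectories()]
#' @export
setClass("TransitionKernel", representation(
  candidates = "list",
  probs      = "list",
  layers     = "list",
  nSteps     = "integer"
))

setValidity("TransitionKernel", function(object) {
  for (t in seq_len(object@nSteps)) {
    pr <- object@probs[[t]]
    for (row in pr) {
      if (any(row < 0)) return("kernel probabilities must be non-negative")
      if (abs(sum(row) - 1) > 1e-12) return("kernel rows must sum to 1 within 1e-12")
    }
  }
  TRUE
})

#' An ensemble of equally long trajectories
#'
#' A matrix with one row per trajectory. \code{kind} is \code{"cell"} when
#' entries index cells of a \linkS4class{CellTable} (with \code{ids} the cell
#' id of each column index) or \code{"token"} when entries are vocabulary
#' token ids. Element t of a trajectory lives in time layer t-1.
#'
#' @seealso [sampleTrajectories()], [encodeTrajectories()], [generateTrajectories()]
#' @export
setClass("TrajectoryEnsemble", representation(
  paths = "matrix",
  kind  = "character",
  ids   = "character"
))

setValidity("TrajectoryEnsemble", function(object) {
  if (!object@kind %in% c("cell", "token"))
    return("kind must be 'cell' or 'token'")
  if (!is.numeric(object@paths)) return("paths must be an integer matrix")
  TRUE
})

#' Per-layer Voronoi vocabulary over configuration space
#'
#' Tokens are centroids of a per-time-layer vector quantization of the
#' configuration vectors; every cell maps to exactly one token of its own
#' layer, so a token identifies a region of state space *and* a time step.
#' \code{tokenLayer}, \code{tokenType} (majority cell type) and
#' \code{tokenCells} (member cell indices) are per-token metadata;
#' \code{cellToToken} maps cell index to token id.
#'
#' @seealso [fitVocabulary()], [encodeTrajectories()]
#' @export
setClass("Vocabulary", representation(
  centroids   = "matrix",
  tokenLayer  = "integer",
  tokenType   = "character",
  tokenCells  = "list",
  cellToToken = "integer",
  cellIds     = "character"
))

setValidity("Vocabulary", function(object) {
  V <- nrow(object@centroids)
  if (length(object@tokenLayer) != V || length(object@tokenCells) != V)
    return("token metadata length must match number of centroids")
  if (any(lengths(object@tokenCells) == 0L))
    return("no empty tokens allowed after fitting")
  if (anyNA(object@cellToToken) || any(object@cellToToken < 1L) ||
      any(object@cellToToken > V))
    return("every cell must map to exactly one token")
  TRUE
})

#' Autoregressive trajectory models
#'
#' Virtual parent of \linkS4class{TabularARModel} and
#' \linkS4class{TransformerARModel}. An ARModel exposes
#' [nextDistribution()] (probability vector over the vocabulary given a
#' prefix) and [stepDistributions()]; the trajectory probability is the chain
#' rule product over steps and the action of a trajectory is its negative
#' log-probability.
#'
#' @export
setClass("ARModel", representation("VIRTUAL",
  vocabSize = "integer",
  seqLength = "integer"
))

#' Empirical back-off autoregressive model
#'
#' Conditional next-token distributions are exact empirical frequencies of
#' the training ensemble for context orders 1..\code{maxOrder} (contexts keyed
#' by the trailing tokens); an unseen context backs off to the longest seen
#' suffix and ultimately to the per-position (layer-wise) marginal. Serves as
#' the exact chain-rule oracle against which the transformer is measured.
#'
#' @seealso [fitTabular()], [markovChainModel()], [uniformModel()]
#' @export
setClass("TabularARModel", contains = "ARModel", representation(
  maxOrder  = "integer",
  contexts  = "list",
  marginals = "list"
))

#' Causal transformer autoregressive model
#'
#' A decoder-only transformer: the input at each position is the sum of a
#' token embedding, a cell-type embedding (the majority type of the token)
#' and a learned position embedding; stacked pre-norm blocks of causal
#' multi-head self-attention and a ReLU MLP feed a final projection to
#' vocabulary logits. Trained by [trainTransformer()] to minimize the mean
#' trajectory action (cross-entropy in nats). Implemented in plain R with
#' hand-written backpropagation (gradient-checked in the test suite).
#'
#' @export
setClass("TransformerARModel", contains = "ARModel", representation(
  params       = "list",
  config       = "list",
  tokenTypeIds = "integer",
  trainingLog  = "data.frame"
))

#' Multipartite trajectory graph
#'
#' Undirected graph whose nodes are (token, layer) states and whose edges
#' connect states consecutive in at least one trajectory, with integer
#' multiplicity equal to the traversal count. Carries both degree notions:
#' simple degree (distinct neighbors) and multiplicity degree (total
#' traversals in plus out).
#'
#' @seealso [buildMultipartiteGraph()], [edgeCurvature()], [curvatureReport()]
#' @export
setClass("LayeredGraph", representation(
  nodes        = "integer",
  layer        = "integer",
  adj          = "list",
  edges        = "data.frame",
  simpleDegree = "numeric",
  multDegree   = "numeric"
))

setValidity("LayeredGraph", function(object) {
  e <- object@edges
  if (nrow(e)) {
    li <- object@layer[match(e$i, object@nodes)]
    lj <- object@layer[match(e$j, object@nodes)]
    if (any(abs(li - lj) != 1L))
      return("every edge must connect consecutive layers")
  }
  TRUE
})

#' Sampler settings for nucleus sampling
#'
#' \code{topK} (keep the k most likely tokens; \code{Inf} = unlimited),
#' \code{topP} (smallest probability-sorted prefix with cumulative mass >=
#' topP), and \code{temperature} (p proportional to p^(1/T)). The defaults
#' (\code{Inf}, 1, 1) make the filter the identity.
#'
#' @seealso [samplerSettings()], [nucleusFilter()]
#' @export
setClass("SamplerSettings", representation(
  topK        = "numeric",
  topP        = "numeric",
  temperature = "numeric"
))

setValidity("SamplerSettings", function(object) {
  if (object@temperature <= 0) return("temperature must be > 0")
  if (object@topP <= 0 || object@topP > 1) return("topP must be in (0, 1]")
  if (object@topK < 1) return("topK must be >= 1")
  TRUE
})

#' Run configuration
#'
#' All tunable stage parameters in one validated object: k of the KNN
#' candidate search, memory decay \code{memoryLambda} in [0,1] and window
#' \code{memoryWindow}, \code{velocityWeight}, number of principal axes
#' \code{nPcs}, per-layer vocabulary size, sampler settings, transformer
#' hyperparameters, and the master \code{seed} from which every stochastic
#' stage derives a named substream.
#'
#' @seealso [runConfig()], [readRunConfig()]
#' @export
setClass("RunConfig", representation(
  knnK           = "integer",
  memoryLambda   = "numeric",
  memoryWindow   = "integer",
  velocityWeight = "numeric",
  nPcs           = "integer",
  vocabSize      = "integer",
  sampler        = "SamplerSettings",
  model          = "list",
  seed           = "integer"
))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@memoryLambda < 0 || object@memoryLambda > 1)
    msg <- c(msg, "memoryLambda must be in [0, 1]")
  if (object@memoryWindow < 1L) msg <- c(msg, "memoryWindow must be >= 1")
  if (object@knnK < 1L) msg <- c(msg, "knnK must be >= 1")
  if (object@velocityWeight < 0) msg <- c(msg, "velocityWeight must be >= 0")
  if (object@nPcs < 1L) msg <- c(msg, "nPcs must be >= 1")
  if (object@vocabSize < 1L) msg <- c(msg, "vocabSize must be >= 1")
  if (object@seed < 0L) msg <- c(msg, "seed must be non-negative")
  if (length(msg)) msg else TRUE
})
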