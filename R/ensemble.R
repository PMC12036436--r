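#' Construct a trajectory ensemble
#'
#' @param paths integer matrix, one trajectory per row; element t is a cell
#'   index (kind "cell") or a token id (kind "token") and lives in layer t-1
#' @param kind "cell" or "token"
#' @param ids for cell ensembles, character cell ids indexed by cell index
#' @return a \linkS4class{TrajectoryEnsemble}
#' @export
trajectoryEnsemble <- function(paths, kind = c("cell", "token"), ids = character()) {
  kind <- match.arg(kind)
  paths <- matrix(as.integer(paths), nrow = nrow(paths))
  methods::new("TrajectoryEnsemble", paths = paths, kind = kind,
               ids = as.character(ids))
}

#' Accessors for TrajectoryEnsemble
#'
#' \code{nTrajectories}: number of trajectories; \code{pathLength}: common
#' length T+1; \code{trajectoryKind}: "cell" or "token";
#' \code{as.matrix}: the underlying integer matrix.
#'
#' @param x a \linkS4class{TrajectoryEnsemble}
#' @name trajectoryAccessors
NULL

#' @rdname trajectoryAccessors
#' @export
setMethod("nTrajectories", "TrajectoryEnsemble", function(x) nrow(x@paths))

#' @rdname trajectoryAccessors
#' @export
setMethod("pathLength", "TrajectoryEnsemble", function(x) ncol(x@paths))

#' @rdname trajectoryAccessors
#' @export
setMethod("trajectoryKind", "TrajectoryEnsemble", function(x) x@kind)

#' @rdname trajectoryAccessors
#' @param ... ignored
#' @export
setMethod("as.matrix", "TrajectoryEnsemble", function(x, ...) x@paths)

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat("TrajectoryEnsemble:", nTrajectories(object), object@kind,
      "trajectories of length", pathLength(object), "\n")
})

#' @rdname configurationAccessors
#' @export
setMethod("configMatrix", "ConfigurationMatrix", function(x) x@coords)

#' Accessors for ConfigurationMatrix
#' @param x a \linkS4class{ConfigurationMatrix}
#' @name configurationAccessors
NULL

setMethod("show", "ConfigurationMatrix", function(object) {
  cat("ConfigurationMatrix:", nrow(object@coords), "cells x",
      ncol(object@coords), "dims (nPcs =", object@nPcs,
      ", velocityWeight =", object@velocityWeight, ")\n")
  if (length(object@droppedGenes))
    cat("  dropped zero-variance genes:", length(object@droppedGenes), "\n")
})

setMethod("show", "TransitionKernel", function(object) {
  cat("TransitionKernel:", object@nSteps, "steps\n")
})

setMethod("show", "SamplerSettings", function(object) {
  cat("SamplerSettings: topK =", object@topK, " topP =", object@topP,
      " temperature =", object@temperature, "\n")
})
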