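#' Next-token distribution of an autoregressive model
#'
#' Returns the model's conditional probability vector over the whole
#' vocabulary for the position following \code{prefix} (an integer token
#' vector; \code{integer(0)} asks for the empty-prefix distribution used for
#' the first step). The returned vector is non-negative and sums to 1.
#'
#' @param model an \linkS4class{ARModel}
#' @param prefix integer vector of preceding tokens (possibly empty)
#' @return numeric vector of length \code{vocabSize(model)}
#' @export
setGeneric("nextDistribution", function(model, prefix) standardGeneric("nextDistribution"))

#' Per-position next-token distributions along a trajectory
#'
#' Row t is the model's distribution for position t given tokens 1..t-1 of
#' \code{tokens}; row 1 is the empty-prefix distribution. For the transformer
#' this is a single forward pass.
#'
#' @param model an \linkS4class{ARModel}
#' @param tokens integer token vector
#' @return numeric matrix, \code{length(tokens)} x \code{vocabSize(model)}
#' @export
setGeneric("stepDistributions", function(model, tokens) standardGeneric("stepDistributions"))

#' @rdname cellTableAccessors
#' @export
setGeneric("expressionMatrix", function(x) standardGeneric("expressionMatrix"))

#' @rdname cellTableAccessors
#' @export
setGeneric("velocityMatrix", function(x) standardGeneric("velocityMatrix"))

#' @rdname cellTableAccessors
#' @export
setGeneric("timeSteps", function(x) standardGeneric("timeSteps"))

#' @rdname cellTableAccessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname cellTableAccessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname cellTableAccessors
#' @export
setGeneric("layerSizes", function(x) standardGeneric("layerSizes"))

#' @rdname cellTableAccessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' @rdname trajectoryAccessors
#' @export
setGeneric("nTrajectories", function(x) standardGeneric("nTrajectories"))

#' @rdname trajectoryAccessors
#' @export
setGeneric("pathLength", function(x) standardGeneric("pathLength"))

#' @rdname trajectoryAccessors
#' @export
setGeneric("trajectoryKind", function(x) standardGeneric("trajectoryKind"))

#' @rdname vocabularyAccessors
#' @export
setGeneric("nTokens", function(x) standardGeneric("nTokens"))

#' @rdname vocabularyAccessors
#' @export
setGeneric("tokenLayer", function(x) standardGeneric("tokenLayer"))

#' @rdname vocabularyAccessors
#' @export
setGeneric("tokenType", function(x) standardGeneric("tokenType"))

#' @rdname vocabularyAccessors
#' @export
setGeneric("cellToToken", function(x) standardGeneric("cellToToken"))

#' @rdname armodelAccessors
#' @export
setGeneric("vocabSize", function(model) standardGeneric("vocabSize"))

#' @rdname armodelAccessors
#' @export
setGeneric("seqLength", function(model) standardGeneric("seqLength"))

#' @rdname armodelAccessors
#' @export
setGeneric("trainingLog", function(model) standardGeneric("trainingLog"))

#' @rdname configurationAccessors
#' @export
setGeneric("configMatrix", function(x) standardGeneric("configMatrix"))
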