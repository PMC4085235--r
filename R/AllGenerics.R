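#' @rdname ReactionSystem-class
#' @param x a \code{ReactionSystem}.
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' @rdname ReactionSystem-class
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))

#' @rdname ReactionSystem-class
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname ReactionSystem-class
#' @export
setGeneric("reactionNames", function(x) standardGeneric("reactionNames"))

#' @rdname ReactionSystem-class
#' @export
setGeneric("rateConstants", function(x) standardGeneric("rateConstants"))

#' @rdname ReactionSystem-class
#' @export
setGeneric("netChange", function(x) standardGeneric("netChange"))

#' @rdname ReactionSystem-class
#' @export
setGeneric("reactantOrders", function(x) standardGeneric("reactantOrders"))

#' @rdname ReactionSystem-class
#' @export
setGeneric("fixedSpecies", function(x) standardGeneric("fixedSpecies"))

#' @rdname Trajectory-class
#' @param x a \code{Trajectory}.
#' @export
setGeneric("trajTimes", function(x) standardGeneric("trajTimes"))

#' @rdname Trajectory-class
#' @export
setGeneric("trajStates", function(x) standardGeneric("trajStates"))

#' @rdname Trajectory-class
#' @export
setGeneric("finalState", function(x) standardGeneric("finalState"))

#' @rdname Trajectory-class
#' @export
setGeneric("stepInfo", function(x) standardGeneric("stepInfo"))

#' @rdname Histogram-class
#' @param x a \code{Histogram}.
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname Histogram-class
#' @export
setGeneric("binProbabilities", function(x) standardGeneric("binProbabilities"))

setMethod("nSpecies", "ReactionSystem", function(x) length(x@speciesNames))
setMethod("nReactions", "ReactionSystem", function(x) length(x@rateConstants))
setMethod("speciesNames", "ReactionSystem", function(x) x@speciesNames)
setMethod("reactionNames", "ReactionSystem", function(x) x@reactionNames)
setMethod("rateConstants", "ReactionSystem", function(x) x@rateConstants)
setMethod("netChange", "ReactionSystem", function(x) x@netChange)
setMethod("reactantOrders", "ReactionSystem", function(x) x@reactantOrders)
setMethod("fixedSpecies", "ReactionSystem", function(x) x@fixedSpecies)

setMethod("trajTimes", "Trajectory", function(x) x@times)
setMethod("trajStates", "Trajectory", function(x) x@states)
setMethod("finalState", "Trajectory", function(x) x@states[nrow(x@states), ])
setMethod("stepInfo", "Trajectory", function(x) x@stepInfo)

setMethod("binEdges", "Histogram", function(x) x@binEdges)
setMethod("binProbabilities", "Histogram", function(x) x@probabilities)
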