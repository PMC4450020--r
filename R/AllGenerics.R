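#' @name multiblockDA-generics
#' @title Accessor generics
#' @description Small accessor generics used across the package's S4 classes.
#' @param x an object.
#' @param ... passed to methods.
#' @keywords internal
NULL

#' @rdname multiblockDA-generics
#' @export
setGeneric("blocks", function(x, ...) standardGeneric("blocks"))

#' @rdname multiblockDA-generics
#' @export
setGeneric("blockNames", function(x, ...) standardGeneric("blockNames"))

#' @rdname multiblockDA-generics
#' @export
setGeneric("nBlocks", function(x, ...) standardGeneric("nBlocks"))

#' @rdname multiblockDA-generics
#' @export
setGeneric("sampleIDs", function(x, ...) standardGeneric("sampleIDs"))

#' @rdname multiblockDA-generics
#' @export
setGeneric("featureNames", function(x, ...) standardGeneric("featureNames"))

#' @rdname multiblockDA-generics
#' @export
setGeneric("classIndex", function(x, ...) standardGeneric("classIndex"))

#' @rdname multiblockDA-generics
#' @export
setGeneric("isPrepared", function(x, ...) standardGeneric("isPrepared"))

#' @rdname multiblockDA-generics
#' @export
setGeneric("designMatrix", function(x, ...) standardGeneric("designMatrix"))

#' @rdname multiblockDA-generics
#' @export
setGeneric("weightMatrix", function(x, ...) standardGeneric("weightMatrix"))

#' @rdname multiblockDA-generics
#' @export
setGeneric("blockLoadings", function(x, ...) standardGeneric("blockLoadings"))

#' @rdname multiblockDA-generics
#' @export
setGeneric("blockScores", function(x, ...) standardGeneric("blockScores"))

#' @rdname multiblockDA-generics
#' @export
setGeneric("blockLambdas", function(x, ...) standardGeneric("blockLambdas"))

#' @rdname multiblockDA-generics
#' @export
setGeneric("objectiveTrace", function(x, ...) standardGeneric("objectiveTrace"))

#' @rdname multiblockDA-generics
#' @export
setGeneric("slackVariables", function(x, ...) standardGeneric("slackVariables"))

#' @rdname multiblockDA-generics
#' @export
setGeneric("nRanks", function(x, ...) standardGeneric("nRanks"))

#' @rdname multiblockDA-generics
#' @export
setGeneric("isConverged", function(x, ...) standardGeneric("isConverged"))

#' @rdname multiblockDA-generics
#' @export
setGeneric("truthMasks", function(x, ...) standardGeneric("truthMasks"))

#' @rdname multiblockDA-generics
#' @export
setGeneric("selectionMetrics", function(x, ...) standardGeneric("selectionMetrics"))

#' @rdname multiblockDA-generics
#' @export
setGeneric("selectionConfusion", function(x, ...) standardGeneric("selectionConfusion"))
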