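#' Accessors
#'
#' Small accessor generics for the package's S4 classes.
#'
#' @param object an S4 object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("basisValues", function(object) standardGeneric("basisValues"))

#' @rdname accessors
#' @export
setMethod("basisValues", "HahnBasis", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("hahnOrder", function(object) standardGeneric("hahnOrder"))

#' @rdname accessors
#' @export
setMethod("hahnOrder", "HahnBasis", function(object) object@N)

#' @rdname accessors
#' @export
setGeneric("firingCounts", function(object) standardGeneric("firingCounts"))

#' @rdname accessors
#' @export
setMethod("firingCounts", "PCNNResult", function(object) object@firingCounts)

#' @rdname accessors
#' @export
setGeneric("firstFire", function(object) standardGeneric("firstFire"))

#' @rdname accessors
#' @export
setMethod("firstFire", "PCNNResult", function(object) object@firstFire)

#' @rdname accessors
#' @export
setGeneric("blockArray", function(object) standardGeneric("blockArray"))

#' @rdname accessors
#' @export
setMethod("blockArray", "BlockGrid", function(object) object@blocks)

#' @rdname accessors
#' @export
setGeneric("blockSide", function(object) standardGeneric("blockSide"))

#' @rdname accessors
#' @export
setMethod("blockSide", "BlockGrid", function(object) object@D)

#' @rdname accessors
#' @export
setGeneric("padding", function(object) standardGeneric("padding"))

#' @rdname accessors
#' @export
setMethod("padding", "BlockGrid", function(object)
    c(rows = object@padRows, cols = object@padCols))

#' @rdname accessors
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))

#' @rdname accessors
#' @export
setMethod("lossHistory", "FusionNetwork", function(object) object@lossHistory)

#' @rdname accessors
#' @export
setGeneric("structural", function(object) standardGeneric("structural"))

#' @rdname accessors
#' @export
setMethod("structural", "PhantomPair", function(object) object@structural)

#' @rdname accessors
#' @export
setGeneric("functional", function(object) standardGeneric("functional"))

#' @rdname accessors
#' @export
setMethod("functional", "PhantomPair", function(object) object@functional)

#' @rdname accessors
#' @export
setGeneric("phantomMeta", function(object) standardGeneric("phantomMeta"))

#' @rdname accessors
#' @export
setMethod("phantomMeta", "PhantomPair", function(object) object@meta)
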