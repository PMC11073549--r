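#' @import methods
NULL

#' Accessor generics
#'
#' Small family of accessors shared by the core containers: signal values,
#' repetition time, frame/region counts, region identifiers and intrinsic
#' system labels, task blocks, and edge indexing.
#'
#' @param x an edgets object
#' @param ... passed to methods
#' @name edgets-accessors
NULL

#' @rdname edgets-accessors
#' @export
setGeneric("signalValues", function(x, ...) standardGeneric("signalValues"))

#' @rdname edgets-accessors
#' @export
setGeneric("repTime", function(x, ...) standardGeneric("repTime"))

#' @rdname edgets-accessors
#' @export
setGeneric("nFrames", function(x, ...) standardGeneric("nFrames"))

#' @rdname edgets-accessors
#' @export
setGeneric("nRegions", function(x, ...) standardGeneric("nRegions"))

#' @rdname edgets-accessors
#' @export
setGeneric("regionIds", function(x, ...) standardGeneric("regionIds"))

#' @rdname edgets-accessors
#' @export
setGeneric("systemLabels", function(x, ...) standardGeneric("systemLabels"))

#' @rdname edgets-accessors
#' @export
setGeneric("taskBlocks", function(x, ...) standardGeneric("taskBlocks"))

#' @rdname edgets-accessors
#' @export
setGeneric("edgePairs", function(x, ...) standardGeneric("edgePairs"))

#' @rdname edgets-accessors
#' @export
setGeneric("nEdges", function(x, ...) standardGeneric("nEdges"))
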