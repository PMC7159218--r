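#' @include AllClasses.R
NULL

#' @rdname SlideFrame-accessors
#' @export
setGeneric("widthPx", function(x) standardGeneric("widthPx"))

#' @rdname SlideFrame-accessors
#' @export
setGeneric("heightPx", function(x) standardGeneric("heightPx"))

#' @rdname SlideFrame-accessors
#' @export
setGeneric("resolutionUmPerPx", function(x) standardGeneric("resolutionUmPerPx"))

#' @rdname SlideFrame-accessors
#' @export
setGeneric("pixelAreaMm2", function(x) standardGeneric("pixelAreaMm2"))

#' Extract the frame of a slide object
#' @param x an object carrying a \linkS4class{SlideFrame}
#' @return the \linkS4class{SlideFrame}
#' @export
setGeneric("slideFrame", function(x) standardGeneric("slideFrame"))

#' Raster pixels of a mask
#' @param x a \linkS4class{BinaryMask} or \linkS4class{LabelMask}
#' @return the underlying matrix (logical or integer)
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))

#' Point coordinates of a PointSet
#' @param x a \linkS4class{PointSet}
#' @return numeric matrix with columns x, y
#' @export
setGeneric("pointCoords", function(x) standardGeneric("pointCoords"))
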