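#' @title Accessor generics
#' @description Generics for the calibration, image, velocity-field and
#'   control-volume classes. Each has methods documented with its class.
#' @param x an object of one of the package's classes
#' @name accessors
#' @keywords internal
NULL

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("refractiveIncrement", function(x) standardGeneric("refractiveIncrement"))

#' @rdname accessors
#' @export
setGeneric("opd", function(x) standardGeneric("opd"))

#' @rdname accessors
#' @export
setGeneric("density", function(x) standardGeneric("density"))

#' @rdname accessors
#' @export
setGeneric("timestamp", function(x) standardGeneric("timestamp"))

#' @rdname accessors
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname accessors
#' @export
setGeneric("maskLabel", function(x) standardGeneric("maskLabel"))

#' @rdname accessors
#' @export
setGeneric("corners", function(x) standardGeneric("corners"))

#' @rdname accessors
#' @export
setGeneric("cvId", function(x) standardGeneric("cvId"))

#' @rdname accessors
#' @export
setGeneric("seedCenter", function(x) standardGeneric("seedCenter"))

#' @rdname accessors
#' @export
setGeneric("trackTable", function(x) standardGeneric("trackTable"))

#' @rdname accessors
#' @export
setGeneric("growthRaster", function(x) standardGeneric("growthRaster"))

#' @rdname accessors
#' @export
setGeneric("analysisWindow", function(x) standardGeneric("analysisWindow"))
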