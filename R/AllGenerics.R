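#' @include AllClasses.R
NULL

#' Accessors for FociTrace classes
#'
#' Small accessor generics following the usual Bioconductor idiom: slots are
#' never reached into directly by user code.
#'
#' @param x an object of the documented class.
#' @param ... further arguments (unused).
#' @return see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cellId", function(x, ...) standardGeneric("cellId"))

#' @rdname accessors
#' @export
setGeneric("cellVertices", function(x, ...) standardGeneric("cellVertices"))

#' @rdname accessors
#' @export
setGeneric("cellLength", function(x, ...) standardGeneric("cellLength"))

#' @rdname accessors
#' @export
setGeneric("cellWidth", function(x, ...) standardGeneric("cellWidth"))

#' @rdname accessors
#' @export
setGeneric("cellArea", function(x, ...) standardGeneric("cellArea"))

#' @rdname accessors
#' @export
setGeneric("cellVolume", function(x, ...) standardGeneric("cellVolume"))

#' @rdname accessors
#' @export
setGeneric("cellTable", function(x, ...) standardGeneric("cellTable"))

#' @rdname accessors
#' @export
setGeneric("foci", function(x, ...) standardGeneric("foci"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(x, ...) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("frameTime", function(x, ...) standardGeneric("frameTime"))

#' @rdname accessors
#' @export
setGeneric("acfLags", function(x, ...) standardGeneric("acfLags"))

#' @rdname accessors
#' @export
setGeneric("acfValues", function(x, ...) standardGeneric("acfValues"))

#' @rdname accessors
#' @export
setGeneric("acfSem", function(x, ...) standardGeneric("acfSem"))

#' @rdname accessors
#' @export
setGeneric("amplitudes", function(x, ...) standardGeneric("amplitudes"))

#' @rdname accessors
#' @export
setGeneric("timescales", function(x, ...) standardGeneric("timescales"))

#' Compute the normalized autocorrelation of a trajectory
#'
#' @param x a numeric trajectory or a [TrajectorySet-class].
#' @param ... passed to methods; see [autocorrelation,numeric-method].
#' @export
setGeneric("autocorrelation", function(x, ...) standardGeneric("autocorrelation"))
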