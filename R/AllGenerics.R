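#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Accessors for the slots of the package's data classes; user code should
#' use these rather than reach into slots.
#'
#' @param object An object of one of the package classes.
#' @param ... Passed to methods.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumber", function(object, ...) standardGeneric("wavenumber"))

#' @rdname accessors
#' @export
setGeneric("irAmplitude", function(object, ...) standardGeneric("irAmplitude"))

#' @rdname accessors
#' @export
setGeneric("pllFrequency", function(object, ...) standardGeneric("pllFrequency"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(object, ...) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("category", function(object, ...) standardGeneric("category"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object, ...) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("sessionId", function(object, ...) standardGeneric("sessionId"))

#' @rdname accessors
#' @export
setGeneric("mapData", function(object, ...) standardGeneric("mapData"))

#' @rdname accessors
#' @export
setGeneric("pixelSizeNm", function(object, ...) standardGeneric("pixelSizeNm"))

#' @rdname accessors
#' @export
setGeneric("fieldOfViewUm", function(object, ...) standardGeneric("fieldOfViewUm"))

#' Retrieve one channel map from a dataset
#'
#' @param object An [AFMIRDataset-class].
#' @param channel Channel name (e.g. \code{"Height"}).
#' @param direction \code{"trace"} or \code{"retrace"}.
#' @return A [ChannelMap-class]; error if absent.
#' @export
setGeneric("getChannel",
           function(object, channel, direction = "trace")
             standardGeneric("getChannel"))

#' @rdname getChannel
#' @export
setGeneric("hasChannel",
           function(object, channel, direction = "trace")
             standardGeneric("hasChannel"))

#' @rdname accessors
#' @export
setGeneric("pairTransform", function(object, ...) standardGeneric("pairTransform"))

#' @rdname accessors
#' @export
setGeneric("isRegistered", function(object, ...) standardGeneric("isRegistered"))

#' @rdname accessors
#' @export
setGeneric("cellLabels", function(object, ...) standardGeneric("cellLabels"))

#' @rdname accessors
#' @export
setGeneric("ibLabels", function(object, ...) standardGeneric("ibLabels"))

#' @rdname accessors
#' @export
setGeneric("ibToCell", function(object, ...) standardGeneric("ibToCell"))

#' @rdname accessors
#' @export
setGeneric("ibTable", function(object, ...) standardGeneric("ibTable"))

#' @rdname accessors
#' @export
setGeneric("trueTransform", function(object, ...) standardGeneric("trueTransform"))

#' @rdname accessors
#' @export
setGeneric("chosenTest", function(object, ...) standardGeneric("chosenTest"))

#' @rdname accessors
#' @export
setGeneric("posthocTable", function(object, ...) standardGeneric("posthocTable"))
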