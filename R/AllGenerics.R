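#' @name dscnet-generics
#' @title Accessor generics
#' @description Accessor generics shared by the dscnet S4 containers.
#' @param x an object.
#' @param ... further arguments for methods.
#' @keywords internal
NULL

#' @rdname dscnet-generics
#' @export
setGeneric("segments", function(x, ...) standardGeneric("segments"))

#' @rdname dscnet-generics
#' @export
setGeneric("subjectIds", function(x, ...) standardGeneric("subjectIds"))

#' @rdname dscnet-generics
#' @export
setGeneric("samplingRate", function(x, ...) standardGeneric("samplingRate"))

#' @rdname dscnet-generics
#' @export
setGeneric("channelNames", function(x, ...) standardGeneric("channelNames"))

#' @rdname dscnet-generics
#' @export
setGeneric("signalData", function(x, ...) standardGeneric("signalData"))

#' @rdname dscnet-generics
#' @export
setGeneric("nSegments", function(x, ...) standardGeneric("nSegments"))

#' @rdname dscnet-generics
#' @export
setGeneric("accuracy", function(x, ...) standardGeneric("accuracy"))

#' @rdname dscnet-generics
#' @export
setGeneric("trainIndices", function(x, ...) standardGeneric("trainIndices"))

#' @rdname dscnet-generics
#' @export
setGeneric("testIndices", function(x, ...) standardGeneric("testIndices"))

#' @rdname dscnet-generics
#' @export
setGeneric("modelConfig", function(x, ...) standardGeneric("modelConfig"))
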