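#' @rdname SpectraSet-class
#' @param object,x an object.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname SpectraSet-class
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname SpectraSet-class
#' @export
setGeneric("refValues", function(x) standardGeneric("refValues"))

#' @rdname SpectraSet-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname SpectraSet-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
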