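#' @rdname featureMz
#' @export
setGeneric("featureMz", function(x) standardGeneric("featureMz"))

#' @rdname featureRt
#' @export
setGeneric("featureRt", function(x) standardGeneric("featureRt"))

#' @rdname featureIds
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname sampleData
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname filterRtWindow
#' @export
setGeneric("filterRtWindow",
           function(x, lo = 100, hi = 1100) standardGeneric("filterRtWindow"))

#' @rdname excludeFedPrecursors
#' @export
setGeneric("excludeFedPrecursors",
           function(x, tol_ppm = 15, masses = fedPrecursorMasses())
             standardGeneric("excludeFedPrecursors"))
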