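#' @rdname gridSpec
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @rdname layerNames
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname getLayer
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))

#' @rdname extractValues
#' @export
setGeneric("extractValues", function(x, xy, layers = NULL) standardGeneric("extractValues"))

#' @rdname standardizeLayers
#' @export
setGeneric("standardizeLayers", function(x, layers = NULL) standardGeneric("standardizeLayers"))

#' @rdname aicc
#' @export
setGeneric("aicc", function(object) standardGeneric("aicc"))

#' @rdname estimates
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' @rdname nSites
#' @export
setGeneric("nSites", function(object) standardGeneric("nSites"))

#' @rdname detections
#' @export
setGeneric("detections", function(object) standardGeneric("detections"))

#' @rdname siteCovs
#' @export
setGeneric("siteCovs", function(object) standardGeneric("siteCovs"))

#' @rdname designData
#' @export
setGeneric("designData", function(object) standardGeneric("designData"))

#' @rdname fixedEffects
#' @export
setGeneric("fixedEffects", function(object) standardGeneric("fixedEffects"))

#' @rdname ranefVariances
#' @export
setGeneric("ranefVariances", function(object) standardGeneric("ranefVariances"))
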