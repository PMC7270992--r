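#' @rdname peakAreas
#' @export
setGeneric("peakAreas", function(x) standardGeneric("peakAreas"))

#' @rdname featureMeta
#' @export
setGeneric("featureMeta", function(x) standardGeneric("featureMeta"))

#' @rdname sampleMeta
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @rdname isQC
#' @export
setGeneric("isQC", function(x) standardGeneric("isQC"))

#' @rdname dilutionQuotients
#' @export
setGeneric("dilutionQuotients", function(x) standardGeneric("dilutionQuotients"))

#' @rdname pqnReference
#' @export
setGeneric("pqnReference", function(x) standardGeneric("pqnReference"))

#' @rdname filterLog
#' @export
setGeneric("filterLog", function(x) standardGeneric("filterLog"))

#' @rdname trueEffects
#' @export
setGeneric("trueEffects", function(x) standardGeneric("trueEffects"))

#' @rdname trueDilutions
#' @export
setGeneric("trueDilutions", function(x) standardGeneric("trueDilutions"))

#' @rdname affectedFeatures
#' @export
setGeneric("affectedFeatures", function(x) standardGeneric("affectedFeatures"))

#' @rdname annotationGroups
#' @export
setGeneric("annotationGroups", function(x) standardGeneric("annotationGroups"))
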