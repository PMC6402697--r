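#' @import methods
NULL

#' Accessor generics
#'
#' Generics for the central containers: per-modality mutation catalogs and
#' fitted topic models. `counts` is re-used from BiocGenerics.
#'
#' @param object an object
#' @param ... further arguments passed to methods
#' @name mmctm-generics
NULL

#' @rdname mmctm-generics
#' @export
setGeneric("modality", function(object, ...) standardGeneric("modality"))

#' @rdname mmctm-generics
#' @export
setGeneric("categories", function(object, ...) standardGeneric("categories"))

#' @rdname mmctm-generics
#' @export
setGeneric("sampleIDs", function(object, ...) standardGeneric("sampleIDs"))

#' @rdname mmctm-generics
#' @export
setGeneric("modalityFeatures", function(object, ...) standardGeneric("modalityFeatures"))

#' @rdname mmctm-generics
#' @export
setGeneric("signatures", function(object, ...) standardGeneric("signatures"))

#' @rdname mmctm-generics
#' @export
setGeneric("sampleProbs", function(object, ...) standardGeneric("sampleProbs"))

#' @rdname mmctm-generics
#' @export
setGeneric("priorMean", function(object, ...) standardGeneric("priorMean"))

#' @rdname mmctm-generics
#' @export
setGeneric("priorCov", function(object, ...) standardGeneric("priorCov"))

#' @rdname mmctm-generics
#' @export
setGeneric("elboTrace", function(object, ...) standardGeneric("elboTrace"))

#' @rdname mmctm-generics
#' @export
setGeneric("trainingLogLik", function(object, ...) standardGeneric("trainingLogLik"))

#' @rdname mmctm-generics
#' @export
setGeneric("nSignatures", function(object, ...) standardGeneric("nSignatures"))

#' @rdname mmctm-generics
#' @export
setGeneric("modalityNames", function(object, ...) standardGeneric("modalityNames"))
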