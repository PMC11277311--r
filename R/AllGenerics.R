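#' @import methods
NULL

#' @rdname VariantSet-class
#' @param object,x a \code{VariantSet}.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname VariantSet-class
#' @export
setGeneric("variantTable", function(object) standardGeneric("variantTable"))

#' @rdname VariantSet-class
#' @export
setGeneric("variantKeys", function(object) standardGeneric("variantKeys"))

#' @rdname VariantSet-class
#' @export
setGeneric("nVariants", function(object) standardGeneric("nVariants"))

#' @rdname VariantSet-class
#' @export
setGeneric("isAnnotated", function(object) standardGeneric("isAnnotated"))

#' @rdname FilterAudit-class
#' @param object a \code{FilterAudit}.
#' @export
setGeneric("levelCounts", function(object) standardGeneric("levelCounts"))

#' @rdname FilterAudit-class
#' @export
setGeneric("removedVariants", function(object) standardGeneric("removedVariants"))

#' @rdname DuoAssignment-class
#' @param object a \code{DuoAssignment}.
#' @export
setGeneric("pairId", function(object) standardGeneric("pairId"))

#' @rdname DuoAssignment-class
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))

#' @rdname DuoAssignment-class
#' @export
setGeneric("rescueEvents", function(object) standardGeneric("rescueEvents"))

#' @rdname MixtureFit-class
#' @param object a \code{MixtureFit}.
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
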