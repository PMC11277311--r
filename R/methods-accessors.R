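## Accessors and show methods; slots are never reached into by user code.

#' @rdname VariantSet-class
#' @export
setMethod("sampleId", "VariantSet", function(object) object@sampleId)

#' @rdname VariantSet-class
#' @export
setMethod("variantTable", "VariantSet", function(object) object@variants)

#' @rdname VariantSet-class
#' @export
setMethod("variantKeys", "VariantSet", function(object)
  makeVariantKey(object@variants))

#' @rdname VariantSet-class
#' @export
setMethod("nVariants", "VariantSet", function(object) nrow(object@variants))

#' @rdname VariantSet-class
#' @export
setMethod("isAnnotated", "VariantSet", function(object) object@annotated)

setMethod("show", "VariantSet", function(object) {
  cat("VariantSet for sample '", object@sampleId, "': ",
      nrow(object@variants), " variant(s), ",
      if (object@annotated) "annotated" else "not annotated", "\n", sep = "")
})

#' @rdname FilterAudit-class
#' @export
setMethod("levelCounts", "FilterAudit", function(object) object@levels)

#' @rdname FilterAudit-class
#' @export
setMethod("removedVariants", "FilterAudit", function(object) object@removed)

setMethod("show", "FilterAudit", function(object) {
  cat("FilterAudit over", nrow(object@levels), "level(s)\n")
  print(object@levels, row.names = FALSE)
})

#' @rdname DuoAssignment-class
#' @export
setMethod("pairId", "DuoAssignment", function(object) object@pairId)

#' @rdname DuoAssignment-class
#' @export
setMethod("assignments", "DuoAssignment", function(object) object@assignments)

#' @rdname DuoAssignment-class
#' @export
setMethod("rescueEvents", "DuoAssignment", function(object) object@rescueEvents)

setMethod("show", "DuoAssignment", function(object) {
  tab <- table(factor(object@assignments$category,
                      levels = c("P_ONLY", "R_ONLY", "SHARED")))
  cat("DuoAssignment for pair '", object@pairId, "': ",
      tab[["P_ONLY"]], " P-only, ", tab[["R_ONLY"]], " R-only, ",
      tab[["SHARED"]], " shared (", nrow(object@rescueEvents),
      " rescue event(s))\n", sep = "")
})

#' @rdname MixtureFit-class
#' @export
setMethod("nComponents", "MixtureFit", function(object) object@nComponents)

setMethod("show", "MixtureFit", function(object) {
  cat("MixtureFit:", object@nComponents, "component(s), family",
      object@family, "\n  means:",
      paste(sprintf("%.3f", object@means), collapse = ", "), "\n")
})

setMethod("show", "SampleMetrics", function(object) {
  cat("SampleMetrics for '", object@sampleId, "': ",
      object@total_mutations, " mutations, ",
      sprintf("%.2f", object@per_mb), " per Mb (log10 ",
      ifelse(is.na(object@log10_per_mb), "NA",
             sprintf("%.2f", object@log10_per_mb)),
      "), MATH ", ifelse(is.na(object@math_score), "NA",
                         sprintf("%.2f", object@math_score)), "\n", sep = "")
})

#' Build the canonical allele-exact variant key
#'
#' Keys are \code{chrom:pos:ref>alt}; all joins (annotation attach, duo
#' categorization, rescue lookup) are exact on this key, so an A>C bundle
#' never attaches to an A>T record at the same site.
#'
#' @param x data.frame with chrom, pos, ref, alt columns.
#' @return character vector of keys.
#' @export
makeVariantKey <- function(x) {
  if (nrow(x) == 0L) return(character(0))
  paste0(x$chrom, ":", x$pos, ":", x$ref, ">", x$alt)
}

## round-half-up at a given number of decimals; report tables use this to
## match conventional table presentation (R's round() is half-to-even)
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
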