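## Readers and writers for the three inputs (VCF calls, annotation TSV,
## gene panel) and the flattened variant TSV output.

#' Construct a VariantSet
#'
#' Builds a \code{\linkS4class{VariantSet}} from a data.frame of per-allele
#' rows. The VAF column is always recomputed from \code{alt_depth /
#' total_depth} (0 when total_depth is 0) regardless of any incoming value:
#' depth, alternate-read and VAF thresholds are applied jointly downstream,
#' so the three must be internally consistent.
#'
#' @param sampleId sample identifier.
#' @param variants data.frame with at least chrom, pos, ref, alt,
#'   total_depth, alt_depth, caller_flags columns.
#' @param annotated logical; \code{TRUE} if annotation columns are present.
#' @return a \code{VariantSet}.
#' @export
VariantSet <- function(sampleId, variants, annotated = FALSE) {
  if (nrow(variants)) {
    variants$pos <- as.integer(variants$pos)
    variants$total_depth <- as.integer(variants$total_depth)
    variants$alt_depth <- as.integer(variants$alt_depth)
    variants$vaf <- ifelse(variants$total_depth > 0L,
                           variants$alt_depth / variants$total_depth, 0)
    rownames(variants) <- NULL
  } else {
    variants <- .emptyVariantFrame(annotated)
  }
  new("VariantSet", sampleId = as.character(sampleId), variants = variants,
      annotated = annotated)
}

.emptyVariantFrame <- function(annotated) {
  v <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                  alt = character(0), total_depth = integer(0),
                  alt_depth = integer(0), vaf = numeric(0),
                  caller_flags = character(0), stringsAsFactors = FALSE)
  if (annotated) for (col in .ANNOT_COLS) {
    v[[col]] <- if (col %in% c("af_1kg", "af_gnomad_exome", "maf_esp"))
      numeric(0)
    else if (col == "dbsnp_common") logical(0)
    else if (col == "cosmic_count") integer(0)
    else character(0)
  }
  v
}

#' Read somatic variant calls from a VCF file
#'
#' Parses a VCF 4.2 file (via \pkg{vcfR}) into a \code{VariantSet} with one
#' row per (site, alternate allele): multiallelic records are split, with
#' the per-allele alternate depth taken from the matching AD entry.
#' FILTER labels other than PASS/"." are copied into \code{caller_flags}
#' (semicolon-separated labels become a comma-joined flag set). VAF is
#' recomputed from AD/DP; any caller AF field is ignored.
#'
#' The FORMAT fields DP and AD are required; a record missing either raises
#' an error naming the offending data line.
#'
#' @param path path to the VCF file.
#' @param sample_id sample identifier for the returned set. The first
#'   genotype column of the VCF is read.
#' @return an unannotated \code{VariantSet}.
#' @export
readVcfVariants <- function(path, sample_id) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  n <- nrow(fix)
  if (is.null(n) || n == 0L)
    return(VariantSet(sample_id, .emptyVariantFrame(FALSE)))
  if (is.null(gt) || ncol(gt) < 2L)
    stop("VCF has no genotype column with DP/AD fields: ", path)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    where <- paste0("data line ", i, " (", fix[i, "CHROM"], ":",
                    fix[i, "POS"], ")")
    fmt <- strsplit(gt[i, 1L], ":", fixed = TRUE)[[1L]]
    val <- strsplit(gt[i, 2L], ":", fixed = TRUE)[[1L]]
    idp <- match("DP", fmt)
    iad <- match("AD", fmt)
    if (is.na(idp) || is.na(iad) || length(val) < max(idp, iad))
      stop("missing DP/AD FORMAT fields at ", where)
    dp <- suppressWarnings(as.integer(val[idp]))
    ad <- suppressWarnings(as.integer(strsplit(val[iad], ",",
                                               fixed = TRUE)[[1L]]))
    if (is.na(dp) || anyNA(ad))
      stop("unparsable DP/AD values at ", where)
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    if (length(ad) != length(alts) + 1L)
      stop("AD field has ", length(ad), " entries for ", length(alts),
           " alternate allele(s) at ", where)
    filt <- fix[i, "FILTER"]
    flags <- if (is.na(filt) || filt %in% c("PASS", ".")) ""
             else paste(strsplit(filt, ";", fixed = TRUE)[[1L]],
                        collapse = ",")
    out[[i]] <- data.frame(chrom = fix[i, "CHROM"],
                           pos = as.integer(fix[i, "POS"]),
                           ref = toupper(fix[i, "REF"]),
                           alt = toupper(alts),
                           total_depth = dp,
                           alt_depth = ad[-1L],
                           vaf = 0,
                           caller_flags = flags,
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  VariantSet(sample_id, do.call(rbind, out))
}

## annotation TSV header, fixed and documented
.ANNOT_TSV_COLS <- c("chrom", "pos", "ref", "alt", .ANNOT_COLS)

#' Read an annotation-bundle table
#'
#' Reads the tab-separated annotation table keyed by (chrom, pos, ref, alt).
#' Empty cells mean missing for the population-frequency fields, the
#' predictor verdicts and the clinical class; missing is distinct from 0.
#' Unknown enum strings, duplicate keys and malformed fractions raise
#' errors.
#'
#' @param path path to the TSV file.
#' @return data.frame with a \code{key} column plus the bundle columns;
#'   suitable for \code{\link{attachAnnotations}}.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(.ANNOT_TSV_COLS, names(raw))
  if (length(missing_cols))
    stop("annotation table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[.ANNOT_TSV_COLS]
  raw$pos <- as.integer(raw$pos)
  key <- makeVariantKey(raw)
  if (anyDuplicated(key))
    stop("duplicate annotation keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))

  asFraction <- function(x, name) {
    out <- rep(NA_real_, length(x))
    filled <- !is.na(x) & nzchar(x)
    val <- suppressWarnings(as.numeric(x[filled]))
    if (anyNA(val) || any(val < 0 | val > 1))
      stop("malformed fraction in column '", name, "'")
    out[filled] <- val
    out
  }
  asEnum <- function(x, allowed, name, allow_missing = FALSE) {
    if (allow_missing) x[!nzchar(x)] <- NA_character_
    bad <- !is.na(x) & !(x %in% allowed)
    if (any(bad))
      stop("unknown value(s) in column '", name, "': ",
           paste(unique(x[bad]), collapse = ", "))
    x
  }

  out <- raw[c("chrom", "pos", "ref", "alt")]
  out$key <- key
  for (col in c("af_1kg", "af_gnomad_exome", "maf_esp"))
    out[[col]] <- asFraction(raw[[col]], col)
  dbc <- tolower(raw$dbsnp_common)
  if (!all(dbc %in% c("true", "false")))
    stop("dbsnp_common must be 'true' or 'false'")
  out$dbsnp_common <- dbc == "true"
  out$seq_ontology <- asEnum(raw$seq_ontology, .SEQ_ONTOLOGIES, "seq_ontology")
  out$effect <- asEnum(raw$effect, .EFFECTS, "effect")
  for (p in .PREDICTORS)
    out[[p]] <- asEnum(raw[[p]], .PREDICTOR_VERDICTS, p, allow_missing = TRUE)
  out$clinical_class <- asEnum(raw$clinical_class, .CLINICAL_CLASSES,
                               "clinical_class", allow_missing = TRUE)
  out$cosmic_ids <- raw$cosmic_ids
  cc <- suppressWarnings(as.integer(raw$cosmic_count))
  if (anyNA(cc) || any(cc < 0L))
    stop("cosmic_count must be a non-negative integer")
  out$cosmic_count <- cc
  out$gene <- toupper(trimws(raw$gene))
  out$gene_role <- asEnum(raw$gene_role, .GENE_ROLES, "gene_role")
  out$hgvs_c <- raw$hgvs_c
  out$hgvs_p <- raw$hgvs_p
  out
}

#' Write an annotation-bundle table
#'
#' Inverse of \code{\link{readAnnotations}}: writes the fixed-header TSV
#' dialect, with \code{NA} rendered as empty cells.
#'
#' @param bundles data.frame as returned by \code{readAnnotations} (the
#'   \code{key} column is dropped if present).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(bundles, path) {
  bundles <- bundles[.ANNOT_TSV_COLS]
  bundles$dbsnp_common <- ifelse(bundles$dbsnp_common, "true", "false")
  utils::write.table(bundles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' The default annotation bundle for unannotated variants
#'
#' All frequency fields, predictor verdicts and clinical class missing,
#' not a common polymorphism, ontology \code{other}, effect \code{none}
#' (so unannotated variants never survive level 2), no catalogue records,
#' no gene assignment.
#'
#' @return one-row data.frame of annotation columns.
#' @export
defaultAnnotationBundle <- function() {
  out <- data.frame(af_1kg = NA_real_, af_gnomad_exome = NA_real_,
                    maf_esp = NA_real_, dbsnp_common = FALSE,
                    seq_ontology = "other", effect = "none",
                    stringsAsFactors = FALSE)
  for (p in .PREDICTORS) out[[p]] <- NA_character_
  out$clinical_class <- NA_character_
  out$cosmic_ids <- ""
  out$cosmic_count <- 0L
  out$gene <- ""
  out$gene_role <- "none"
  out$hgvs_c <- ""
  out$hgvs_p <- ""
  out
}

#' Attach annotation bundles to variant records
#'
#' Allele-exact left join of bundles onto records by (chrom, pos, ref, alt):
#' the record set is unchanged (no drops, no duplication) and records
#' without a matching bundle receive \code{default_policy}.
#'
#' @param records an unannotated (or annotated) \code{VariantSet}.
#' @param bundles data.frame from \code{\link{readAnnotations}}.
#' @param default_policy one-row data.frame of annotation columns assigned
#'   to unmatched records; default \code{\link{defaultAnnotationBundle}()}.
#' @return an annotated \code{VariantSet} with the same records.
#' @export
attachAnnotations <- function(records, bundles,
                              default_policy = defaultAnnotationBundle()) {
  stopifnot(is(records, "VariantSet"))
  v <- variantTable(records)[.CORE_COLS]
  if (nrow(v) == 0L)
    return(VariantSet(sampleId(records), v, annotated = TRUE))
  idx <- match(makeVariantKey(v), bundles$key)
  for (col in .ANNOT_COLS) {
    vals <- bundles[[col]][idx]
    vals[is.na(idx)] <- default_policy[[col]]
    v[[col]] <- vals
  }
  VariantSet(sampleId(records), v, annotated = TRUE)
}

#' Read a gene panel file
#'
#' One symbol per line; \code{#} starts a comment; blank lines ignored.
#' Symbols are trimmed, upper-cased and de-duplicated. A file with no
#' symbols is an error.
#'
#' @param path path to the panel file.
#' @param name panel name; defaults to the file name.
#' @return a \code{\linkS4class{GenePanel}}.
#' @export
readGenePanel <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  symbols <- unique(toupper(lines[nzchar(lines)]))
  if (length(symbols) == 0L)
    stop("gene panel file contains no symbols: ", path)
  new("GenePanel", symbols = symbols, name = name)
}

#' @rdname GenePanel-class
#' @param object,x a \code{GenePanel}.
#' @export
panelSymbols <- function(object) object@symbols

setMethod("show", "GenePanel", function(object) {
  cat("GenePanel '", object@name, "': ", length(object@symbols),
      " symbol(s)\n", sep = "")
})

#' Write a flattened variant table
#'
#' One TSV row per record with all core and annotation fields; \code{NA}
#' rendered as empty cells.
#'
#' @param records a \code{VariantSet}.
#' @param path output path.
#' @param extra optional data.frame of per-record columns to append (e.g.
#'   oncogenicity calls); must have one row per record.
#' @return \code{path}, invisibly.
#' @export
writeVariantTable <- function(records, path, extra = NULL) {
  v <- variantTable(records)
  out <- cbind(data.frame(sample_id = rep(sampleId(records), nrow(v)),
                          key = makeVariantKey(v),
                          stringsAsFactors = FALSE), v)
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == nrow(v))
    out <- cbind(out, extra)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
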