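# Builders for small in-code fixtures: VCF text, annotated records and
# boundary-case variants. Everything is generated at test time.

# write a minimal single-sample VCF; rows = list of character vectors
# c(chrom, pos, ref, alt, filter, dp, ad) with ad = "ref,alt[,alt2]"
writeTestVcf <- function(rows, path = tempfile(fileext = ".vcf"),
                         sample = "S1", format = "GT:DP:AD",
                         gt_fun = function(r)
                           paste0("0/1:", r[6], ":", r[7])) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", sample, sep = "\t"))
  body <- vapply(rows, function(r)
    paste(r[1], r[2], ".", r[3], r[4], ".", r[5], ".", format, gt_fun(r),
          sep = "\t"), character(1))
  writeLines(c(header, body), path)
  path
}

# one fully annotated variant row; defaults pass every cascade level
annotatedVariant <- function(chrom = "1", pos = 1000L, ref = "A",
                             alt = "T", total_depth = 100L,
                             alt_depth = 30L, caller_flags = "",
                             af_1kg = NA_real_,
                             af_gnomad_exome = NA_real_,
                             maf_esp = NA_real_, dbsnp_common = FALSE,
                             seq_ontology = "missense",
                             effect = "missense", n_damaging = 3L,
                             clinical_class = NA_character_,
                             cosmic_ids = "COSM1", cosmic_count = 20L,
                             gene = "TP53",
                             gene_role = "tumor_suppressor") {
  v <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                  alt = alt, total_depth = as.integer(total_depth),
                  alt_depth = as.integer(alt_depth), vaf = 0,
                  caller_flags = caller_flags, af_1kg = af_1kg,
                  af_gnomad_exome = af_gnomad_exome, maf_esp = maf_esp,
                  dbsnp_common = dbsnp_common, seq_ontology = seq_ontology,
                  effect = effect, stringsAsFactors = FALSE)
  preds <- c("sift", "polyphen2_hvar", "mutation_taster",
             "mutation_assessor", "fathmm", "fathmm_mkl")
  for (i in seq_along(preds))
    v[[preds[i]]] <- if (i <= n_damaging) "damaging" else "tolerated"
  v$clinical_class <- clinical_class
  v$cosmic_ids <- cosmic_ids
  v$cosmic_count <- as.integer(cosmic_count)
  v$gene <- gene
  v$gene_role <- gene_role
  v$hgvs_c <- ""
  v$hgvs_p <- ""
  v
}

# stack annotated variant rows into an annotated VariantSet
annotatedSet <- function(rows, sample_id = "S1") {
  VariantSet(sample_id, do.call(rbind, rows), annotated = TRUE)
}

# spreadsheet-style half-up rounding, independent of package internals
roundHalfUpTest <- function(x, d) sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d

testPanel <- function(symbols = c("TP53", "PTEN", "EGFR")) {
  path <- tempfile(fileext = ".txt")
  writeLines(symbols, path)
  readGenePanel(path)
}
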