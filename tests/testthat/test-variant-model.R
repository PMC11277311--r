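test_that("VCF reading maps depth fields and recomputes VAF", {
  path <- writeTestVcf(list(c("1", "100", "A", "T", "PASS", "100", "80,20")))
  vs <- readVcfVariants(path, "s1")
  expect_s4_class(vs, "VariantSet")
  v <- variantTable(vs)
  expect_equal(nrow(v), 1L)
  expect_equal(v$total_depth, 100L)
  expect_equal(v$alt_depth, 20L)
  expect_equal(v$vaf, 0.20)
  expect_equal(v$caller_flags, "")
})

test_that("non-PASS FILTER labels become caller flags", {
  path <- writeTestVcf(list(
    c("1", "100", "A", "T", "strand_bias", "100", "80,20"),
    c("1", "200", "G", "C", "strand_bias;fragment", "90", "60,30"),
    c("1", "300", "G", "A", ".", "90", "60,30")))
  v <- variantTable(readVcfVariants(path, "s1"))
  expect_equal(v$caller_flags,
               c("strand_bias", "strand_bias,fragment", ""))
})

test_that("multiallelic records split into one row per alt, conserving alleles", {
  tri <- writeTestVcf(list(c("2", "500", "A", "C,T", "PASS", "120",
                             "70,30,20")))
  split2 <- writeTestVcf(list(
    c("2", "500", "A", "C", "PASS", "120", "70,30"),
    c("2", "500", "A", "T", "PASS", "120", "70,20")))
  v_tri <- variantTable(readVcfVariants(tri, "s1"))
  v_split <- variantTable(readVcfVariants(split2, "s1"))
  expect_equal(nrow(v_tri), 2L)
  # identical to the hand-split two-line VCF
  expect_equal(v_tri, v_split)
  expect_equal(v_tri$chrom, c("2", "2"))
  expect_equal(v_tri$ref, c("A", "A"))
  expect_equal(v_tri$vaf, c(30, 20) / 120)
})

test_that("missing or malformed depth fields raise errors naming the line", {
  no_ad <- writeTestVcf(list(c("1", "100", "A", "T", "PASS", "100", "")),
                        format = "GT:DP",
                        gt_fun = function(r) paste0("0/1:", r[6]))
  expect_error(readVcfVariants(no_ad, "s1"), "DP/AD.*line 1",
               ignore.case = TRUE)
  bad_ad <- writeTestVcf(list(c("1", "100", "A", "T", "PASS", "100",
                                "80,xx")))
  expect_error(readVcfVariants(bad_ad, "s1"), "unparsable")
})

test_that("annotation tables round-trip through the TSV dialect", {
  set.seed(11)
  n <- 50L
  rows <- lapply(seq_len(n), function(i)
    annotatedVariant(chrom = as.character(sample(1:22, 1)),
                     pos = 1000L + i,
                     af_1kg = if (i %% 3 == 0) NA_real_ else round(i / 200, 4),
                     dbsnp_common = i %% 4 == 0,
                     n_damaging = i %% 7,
                     clinical_class = if (i %% 5 == 0) "benign"
                                      else NA_character_,
                     cosmic_ids = if (i %% 2 == 0) "" else paste0("COSM", i),
                     cosmic_count = i,
                     gene = paste0("G", i)))
  tab <- do.call(rbind, rows)
  ann_cols <- setdiff(names(tab), c("total_depth", "alt_depth", "vaf",
                                    "caller_flags"))
  path <- tempfile(fileext = ".tsv")
  writeAnnotations(tab[ann_cols], path)
  back <- readAnnotations(path)
  for (col in ann_cols)
    expect_equal(back[[col]], tab[[col]], info = col)
})

test_that("annotation reading rejects bad input", {
  good <- annotatedVariant()
  ann_cols <- setdiff(names(good), c("total_depth", "alt_depth", "vaf",
                                     "caller_flags"))
  dup <- rbind(good, good)[ann_cols]
  p1 <- tempfile(fileext = ".tsv")
  writeAnnotations(dup, p1)
  expect_error(readAnnotations(p1), "duplicate")

  bad_enum <- good[ann_cols]
  bad_enum$seq_ontology <- "nonsense_word"
  p2 <- tempfile(fileext = ".tsv")
  suppressWarnings(writeAnnotations(bad_enum, p2))
  expect_error(readAnnotations(p2), "seq_ontology")

  bad_frac <- good[ann_cols]
  bad_frac$af_1kg <- 0.5
  p3 <- tempfile(fileext = ".tsv")
  writeAnnotations(bad_frac, p3)
  txt <- readLines(p3)
  txt[2] <- sub("0.5", "half", txt[2])
  writeLines(txt, p3)
  expect_error(readAnnotations(p3), "fraction")
})

test_that("empty annotation cells mean missing, distinct from zero", {
  good <- annotatedVariant(af_1kg = NA_real_)
  ann_cols <- setdiff(names(good), c("total_depth", "alt_depth", "vaf",
                                     "caller_flags"))
  path <- tempfile(fileext = ".tsv")
  writeAnnotations(good[ann_cols], path)
  back <- readAnnotations(path)
  expect_true(is.na(back$af_1kg))
  zero <- good[ann_cols]
  zero$af_1kg <- 0
  writeAnnotations(zero, path)
  expect_identical(readAnnotations(path)$af_1kg, 0)
})

test_that("annotation attach is an allele-exact left join", {
  path <- writeTestVcf(lapply(1:10, function(i)
    c("1", as.character(100 * i), "A", "T", "PASS", "100", "80,20")))
  recs <- readVcfVariants(path, "s1")
  bundles <- do.call(rbind, lapply(1:7, function(i)
    annotatedVariant(pos = 100L * i, gene = paste0("G", i))))
  ann_cols <- setdiff(names(bundles), c("total_depth", "alt_depth", "vaf",
                                        "caller_flags"))
  tf <- tempfile(fileext = ".tsv")
  writeAnnotations(bundles[ann_cols], tf)
  annotated <- attachAnnotations(recs, readAnnotations(tf))
  expect_equal(nVariants(annotated), 10L)
  v <- variantTable(annotated)
  expect_equal(sum(v$gene != ""), 7L)          # 3 records carry the default
  expect_equal(v$effect[8:10], rep("none", 3))

  # allele-exact: an A>C bundle never attaches to the A>T record
  other_allele <- annotatedVariant(pos = 100L, alt = "C", gene = "WRONG")
  tf2 <- tempfile(fileext = ".tsv")
  writeAnnotations(other_allele[ann_cols], tf2)
  ann2 <- attachAnnotations(recs, readAnnotations(tf2))
  expect_false("WRONG" %in% variantTable(ann2)$gene)
})

test_that("gene panels are read case-normalized and de-duplicated", {
  p <- tempfile()
  writeLines(c("TP53", "PTEN", "tp53", "# comment", "", "  EGFR  "), p)
  panel <- readGenePanel(p)
  expect_setequal(panelSymbols(panel), c("TP53", "PTEN", "EGFR"))

  blank <- tempfile()
  writeLines(c("", "# only comments", "   "), blank)
  expect_error(readGenePanel(blank), "no symbols")
})

test_that("VariantSet enforces its evidence invariants", {
  bad <- annotatedVariant(total_depth = 10L, alt_depth = 20L)
  expect_error(VariantSet("s", bad, annotated = TRUE), "alt_depth")
  multi <- annotatedVariant(alt = "A,T")
  expect_error(VariantSet("s", multi, annotated = TRUE), "multiallelic")
  # vaf is recomputed even when the input column disagrees
  v <- annotatedVariant(total_depth = 100L, alt_depth = 25L)
  v$vaf <- 0.9
  vs <- VariantSet("s", v, annotated = TRUE)
  expect_equal(variantTable(vs)$vaf, 0.25)
})
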