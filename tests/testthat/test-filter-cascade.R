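test_that("level 1 retains records at the inclusive evidence boundaries", {
  boundary <- annotatedVariant(total_depth = 50L, alt_depth = 20L)
  # DP = 50, alt = 20, VAF = 0.40 >= 0.15: all inclusive retentions
  res <- level1QualityFilter(annotatedSet(list(boundary)))
  expect_equal(res$n_passing, 1L)

  # exact VAF boundary: DP 100, alt 20 has VAF 0.20; craft VAF exactly 0.15
  vaf_edge <- annotatedVariant(total_depth = 200L, alt_depth = 30L)
  expect_equal(level1QualityFilter(annotatedSet(list(vaf_edge)))$n_passing,
               1L)

  below <- list(
    depth = annotatedVariant(total_depth = 49L, alt_depth = 20L),
    alt_reads = annotatedVariant(total_depth = 120L, alt_depth = 19L),
    vaf = annotatedVariant(total_depth = 200L, alt_depth = 29L))
  for (nm in names(below)) {
    res <- level1QualityFilter(annotatedSet(list(below[[nm]])))
    expect_equal(res$n_passing, 0L, info = nm)
    expect_equal(res$removed$reason, nm, info = nm)
  }
})

test_that("population frequencies remove at >= threshold and keep missing", {
  at_thr <- annotatedVariant(af_gnomad_exome = 0.02)
  res <- level1QualityFilter(annotatedSet(list(at_thr)))
  expect_equal(res$removed$reason, "pop_af_gnomad")

  just_below <- annotatedVariant(af_gnomad_exome = 0.0199,
                                 af_1kg = 0.0199, maf_esp = 0.0499)
  expect_equal(level1QualityFilter(
    annotatedSet(list(just_below)))$n_passing, 1L)

  missing_af <- annotatedVariant()  # all frequency fields NA
  expect_equal(level1QualityFilter(
    annotatedSet(list(missing_af)))$n_passing, 1L)

  esp <- annotatedVariant(maf_esp = 0.05)
  expect_equal(level1QualityFilter(
    annotatedSet(list(esp)))$removed$reason, "pop_maf_esp")

  dbsnp <- annotatedVariant(dbsnp_common = TRUE)
  expect_equal(level1QualityFilter(
    annotatedSet(list(dbsnp)))$removed$reason, "dbsnp_common")
})

test_that("caller hard-filter flags are removed first", {
  flagged <- annotatedVariant(caller_flags = "strand_bias",
                              total_depth = 10L, alt_depth = 1L)
  res <- level1QualityFilter(annotatedSet(list(flagged)))
  expect_equal(res$removed$reason, "caller_flag")
  frag <- annotatedVariant(caller_flags = "weak_evidence,fragment")
  expect_equal(level1QualityFilter(
    annotatedSet(list(frag)))$removed$reason, "caller_flag")
  # an unlisted flag alone is not excluded
  other <- annotatedVariant(caller_flags = "weak_evidence")
  expect_equal(level1QualityFilter(
    annotatedSet(list(other)))$n_passing, 1L)
})

test_that("damaging-vote counting ignores missing verdicts", {
  all6 <- annotatedVariant(n_damaging = 6L)
  none <- annotatedVariant(n_damaging = 0L)
  missing <- annotatedVariant()
  for (p in c("sift", "polyphen2_hvar", "mutation_taster",
              "mutation_assessor", "fathmm", "fathmm_mkl"))
    missing[[p]] <- NA_character_
  tab <- rbind(all6, none, missing)
  expect_equal(countDamagingVotes(tab), c(6L, 0L, 0L))
})

test_that("level 2 removes irrelevant consequences with ordered reasons", {
  cases <- list(
    list(v = annotatedVariant(seq_ontology = "synonymous"),
         reason = "ontology"),
    list(v = annotatedVariant(n_damaging = 0L), reason = "prediction"),
    list(v = annotatedVariant(clinical_class = "likely_benign"),
         reason = "clinical_class"),
    list(v = annotatedVariant(effect = "none"), reason = "effect"),
    list(v = annotatedVariant(cosmic_ids = ""), reason = "cosmic"))
  for (cs in cases) {
    res <- level2RelevanceFilter(annotatedSet(list(cs$v)))
    expect_equal(res$removed$reason, cs$reason)
  }
  # one damaging vote, clinical class "other", one catalogue ID: retained
  keeper <- annotatedVariant(n_damaging = 1L, clinical_class = "other",
                             cosmic_ids = "COSM9", cosmic_count = 1L)
  expect_equal(level2RelevanceFilter(
    annotatedSet(list(keeper)))$n_passing, 1L)
})

test_that("level 3 keeps panel genes with retained cancer-gene roles", {
  panel <- testPanel(c("TP53", "PTEN", "EGFR"))
  tp53 <- annotatedVariant(gene = "TP53", gene_role = "tumor_suppressor")
  no_role <- annotatedVariant(gene = "TP53", gene_role = "none")
  off_panel <- annotatedVariant(gene = "KRAS", gene_role = "oncogene")
  res <- level3PanelFilter(annotatedSet(list(tp53, no_role, off_panel)),
                           panel)
  expect_equal(res$n_passing, 1L)
  expect_equal(res$removed$reason, c("gene_role", "panel"))
})

test_that("cascade is monotone, idempotent and conserves audit counts", {
  set.seed(7)
  rows <- lapply(1:40, function(i)
    annotatedVariant(pos = 1000L + i,
                     total_depth = sample(30:250, 1),
                     alt_depth = sample(5:60, 1),
                     caller_flags = sample(c("", "strand_bias"), 1,
                                           prob = c(0.8, 0.2)),
                     seq_ontology = sample(c("missense", "synonymous",
                                             "intron"), 1),
                     n_damaging = sample(0:6, 1),
                     cosmic_ids = sample(c("", "COSM1"), 1),
                     gene = sample(c("TP53", "PTEN", "OFFPANEL"), 1),
                     gene_role = sample(c("tumor_suppressor", "none"), 1)))
  rows <- lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    r$alt_depth <- min(r$alt_depth, r$total_depth)
    r
  })
  recs <- annotatedSet(rows)
  panel <- testPanel()
  res <- applyCascade(recs, panel)
  lv <- levelCounts(res$audit)

  # subset monotonicity and count conservation across levels
  expect_true(all(lv$passing <= lv$entering))
  expect_equal(lv$entering[-1], lv$passing[-3])
  removed <- removedVariants(res$audit)
  expect_equal(nrow(removed), lv$entering[1] - lv$passing[3])
  tally <- table(factor(removed$level, levels = 1:3))
  expect_equal(as.integer(tally), lv$entering - lv$passing)
  # passing keys are a subset of input keys
  expect_true(all(variantKeys(res$passing) %in% variantKeys(recs)))

  # idempotence: running the cascade on its own output changes nothing
  res2 <- applyCascade(res$passing, panel)
  expect_equal(variantKeys(res2$passing), variantKeys(res$passing))
  expect_equal(nrow(removedVariants(res2$audit)), 0L)

  # order-independence within levels: permuting input rows gives the
  # same passing set and the same per-variant reasons
  perm <- sample(seq_along(rows))
  res_p <- applyCascade(annotatedSet(rows[perm]), panel)
  expect_setequal(variantKeys(res_p$passing), variantKeys(res$passing))
  a <- removed[order(removed$key), ]
  b <- removedVariants(res_p$audit)
  b <- b[order(b$key), ]
  expect_equal(a$reason, b$reason)
})

test_that("a level-1-only run reproduces the quality-filtered set", {
  rows <- list(annotatedVariant(pos = 1L, seq_ontology = "synonymous"),
               annotatedVariant(pos = 2L),
               annotatedVariant(pos = 3L, total_depth = 40L,
                                alt_depth = 20L))
  recs <- annotatedSet(rows)
  lvl1 <- applyCascade(recs, levels = 1L)
  expect_equal(levelCounts(lvl1$audit)$level, 1L)
  expect_equal(nVariants(lvl1$passing), 2L)  # synonymous passes level 1
  direct <- level1QualityFilter(recs)
  expect_equal(variantKeys(lvl1$passing), variantKeys(direct$passing))
})

test_that("filter configuration round-trips through YAML identically", {
  cfg <- FilterConfig(min_depth = 30L, min_vaf = 0.1,
                      excluded_caller_flags = c("strand_bias"))
  path <- tempfile(fileext = ".yaml")
  writeFilterConfig(cfg, path)
  back <- readFilterConfig(path)
  for (s in slotNames("FilterConfig"))
    expect_identical(slot(back, s), slot(cfg, s), info = s)

  # identical cascade results under the reloaded config
  rows <- list(annotatedVariant(pos = 1L, total_depth = 35L,
                                alt_depth = 21L),
               annotatedVariant(pos = 2L, total_depth = 29L,
                                alt_depth = 21L))
  recs <- annotatedSet(rows)
  panel <- testPanel()
  expect_equal(
    variantKeys(applyCascade(recs, panel, back)$passing),
    variantKeys(applyCascade(recs, panel, cfg)$passing))
})

test_that("empty input passes through the cascade with an all-zero audit", {
  empty <- VariantSet("s0", data.frame(), annotated = TRUE)
  res <- applyCascade(empty, testPanel())
  expect_equal(nVariants(res$passing), 0L)
  lv <- levelCounts(res$audit)
  expect_equal(lv$entering, c(0L, 0L, 0L))
  expect_equal(lv$passing, c(0L, 0L, 0L))
})

test_that("review report ranks by score then catalogue count", {
  rows <- list(
    annotatedVariant(pos = 1L, cosmic_count = 10L),   # mid score
    annotatedVariant(pos = 2L, effect = "LoF", cosmic_count = 80L),
    annotatedVariant(pos = 3L, effect = "LoF", cosmic_count = 60L))
  recs <- annotatedSet(rows)
  calls <- scoreVariants(recs)
  path <- tempfile(fileext = ".tsv")
  writeReviewReport(recs, calls, path)
  rep <- read.delim(path)
  expect_equal(nrow(rep), 3L)
  expect_true(all(diff(rep$score) <= 0))
  same_score <- rep[rep$score == max(rep$score), ]
  expect_true(all(diff(same_score$cosmic_count) <= 0))
})
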