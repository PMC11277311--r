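test_that("simulation is byte-identical for a fixed seed", {
  d1 <- tempfile("sa"); d2 <- tempfile("sb")
  s1 <- simulateDuo(SimConfig(seed = 5L), d1)
  s2 <- simulateDuo(SimConfig(seed = 5L), d2)
  for (f in c("vcf_P", "vcf_R", "annotations", "panel", "truth_tsv"))
    expect_identical(readLines(s1[[f]]), readLines(s2[[f]]), info = f)
  s3 <- simulateDuo(SimConfig(seed = 6L), tempfile("sc"))
  expect_false(identical(readLines(s1$vcf_P), readLines(s3$vcf_P)))
})

test_that("planted structure matches the configuration", {
  cfg <- SimConfig(seed = 9L, n_trunk = 6L, n_private_P = 10L,
                   n_private_R = 12L, n_artifacts_P = 5L,
                   n_artifacts_R = 4L, n_polymorphisms = 3L,
                   n_rescue_trunk = 2L)
  sim <- simulateDuo(cfg, tempfile())
  occ <- sim$truth@occurrences
  per_variant <- occ[!duplicated(occ$key), ]
  expect_equal(sum(per_variant$origin == "trunk"), 6L)
  expect_equal(sum(per_variant$origin == "private_P"), 10L)
  expect_equal(sum(per_variant$origin == "private_R"), 12L)
  expect_equal(sum(per_variant$origin == "artifact"), 9L)
  expect_equal(sum(per_variant$origin == "polymorphism"), 3L)
  expect_equal(sum(per_variant$rescue_planted), 2L)

  # trunk and polymorphism variants occur in both samples; privates in one
  tab <- table(occ$key)
  expect_true(all(tab[per_variant$key[per_variant$origin %in%
                                        c("trunk", "polymorphism")]] == 2L))
  expect_true(all(tab[per_variant$key[per_variant$origin %in%
                                        c("private_P", "private_R")]] == 1L))

  # artifacts are C>T with an excluded caller flag at low VAF
  art <- occ[occ$origin == "artifact", ]
  expect_true(all(art$ref == "C" & art$alt == "T"))
  expect_true(all(art$caller_flags %in% c("strand_bias", "fragment")))
  expect_true(all(art$vaf <= 0.11))

  # polymorphisms carry >= 2% population AF and dbSNP-common membership
  ann <- sim$truth@annotations
  ann$key <- makeVariantKey(ann)
  poly <- ann[ann$key %in% per_variant$key[per_variant$origin ==
                                             "polymorphism"], ]
  expect_true(all(poly$af_1kg >= 0.02 & poly$dbsnp_common))
})

test_that("written VCF/annotation files reproduce the truth occurrences", {
  sim <- simulateDuo(SimConfig(seed = 3L), tempfile())
  occ <- sim$truth@occurrences
  for (s in c("P", "R")) {
    vs <- readVcfVariants(sim[[paste0("vcf_", s)]], s)
    v <- variantTable(vs)
    o <- occ[occ$sample == s, ]
    o <- o[order(o$key), ]
    v <- v[order(makeVariantKey(v)), ]
    expect_equal(nrow(v), nrow(o))
    expect_equal(v$total_depth, o$total_depth)
    expect_equal(v$alt_depth, o$alt_depth)
    expect_equal(v$vaf, o$vaf)
    expect_equal(v$caller_flags, o$caller_flags)
  }
})

test_that("clone VAFs concentrate at their centers", {
  cfg <- SimConfig(seed = 11L, n_trunk = 60L, n_private_P = 0L,
                   n_private_R = 0L, n_artifacts_P = 0L,
                   n_artifacts_R = 0L, n_polymorphisms = 0L,
                   clone_vaf_centers_P = c(0.25, 0.45),
                   clone_vaf_centers_R = c(0.25, 0.45),
                   n_rescue_trunk = 0L, clone_sd = 0.02)
  sim <- simulateDuo(cfg, tempfile())
  occ <- sim$truth@occurrences
  for (cl in 1:2) {
    sel <- occ$clone == cl & occ$sample == "P"
    center <- c(0.25, 0.45)[cl]
    n <- sum(sel)
    expect_lt(abs(mean(occ$vaf[sel]) - center), 2 * 0.02 / sqrt(n) + 0.01)
  }
  # near-degenerate clone spread drives MATH toward 0
  tight <- simulateDuo(SimConfig(seed = 12L, n_trunk = 40L,
                                 n_private_P = 0L, n_private_R = 0L,
                                 n_artifacts_P = 0L, n_artifacts_R = 0L,
                                 n_polymorphisms = 0L,
                                 clone_vaf_centers_P = 0.4,
                                 clone_vaf_centers_R = 0.4,
                                 clone_sd = 1e-4, n_rescue_trunk = 0L),
                       tempfile())
  vafs <- tight$truth@occurrences$vaf[tight$truth@occurrences$sample == "P"]
  expect_lt(mathScore(vafs), 2)
})

test_that("no artifacts means no caller-flag removals at level 1", {
  cfg <- SimConfig(seed = 21L, n_artifacts_P = 0L, n_artifacts_R = 0L)
  sim <- simulateDuo(cfg, tempfile())
  res <- runDuoPipeline(sim$vcf_P, sim$vcf_R, sim$annotations, sim$panel)
  removed <- rbind(removedVariants(res$audit_P),
                   removedVariants(res$audit_R))
  expect_equal(sum(removed$reason == "caller_flag"), 0L)
})

test_that("zero panel fraction yields zero level-3 survivors", {
  cfg <- SimConfig(seed = 22L, panel_fraction = 0, n_rescue_trunk = 0L)
  sim <- simulateDuo(cfg, tempfile())
  exp <- expectedCounts(sim$truth)
  expect_equal(exp$audit_P$passing[3], 0L)
  expect_equal(exp$audit_R$passing[3], 0L)
  res <- runDuoPipeline(sim$vcf_P, sim$vcf_R, sim$annotations, sim$panel)
  expect_equal(nVariants(res$passing_P), 0L)
  expect_equal(nVariants(res$passing_R), 0L)
})

test_that("rescuable trunk variants are planted exactly as advertised", {
  cfg <- SimConfig(seed = 33L, n_trunk = 5L, panel_fraction = 1,
                   n_rescue_trunk = 1L, n_private_P = 0L,
                   n_private_R = 0L)
  sim <- simulateDuo(cfg, tempfile())
  occ <- sim$truth@occurrences
  resc <- occ[occ$rescue_planted & occ$sample == "R", ]
  expect_equal(nrow(resc), 1L)
  # below the level-1 VAF threshold, above the rescue floor
  expect_lt(resc$vaf, 0.15)
  expect_gte(resc$vaf, 0.05)
  expect_gte(resc$alt_depth, 5L)

  # with all trunk variants qualifying drivers, all 5 end up SHARED
  res <- runDuoPipeline(sim$vcf_P, sim$vcf_R, sim$annotations, sim$panel)
  a <- assignments(res$assignment)
  trunk_keys <- unique(occ$key[occ$origin == "trunk"])
  expect_setequal(a$key[a$category == "SHARED"], trunk_keys)
  expect_equal(sum(a$category == "SHARED"), 5L)
  expect_equal(rescueEvents(res$assignment)$key,
               unique(occ$key[occ$rescue_planted]))
})

test_that("with rescue disabled, shared equals independently passing trunk", {
  cfg <- SimConfig(seed = 41L)
  sim <- simulateDuo(cfg, tempfile())
  no_rescue <- RescueConfig(min_partner_alt_reads = 10000L,
                            min_partner_vaf = 1)
  exp <- expectedCounts(sim$truth, rescue_config = no_rescue)
  res <- runDuoPipeline(sim$vcf_P, sim$vcf_R, sim$annotations, sim$panel,
                        rescue_config = no_rescue)
  a <- assignments(res$assignment)
  expect_equal(sort(a$key[a$category == "SHARED"]),
               sort(exp$categories$key[exp$categories$category ==
                                         "SHARED"]))
})

test_that("pipeline equals the enumeration oracle across random seeds", {
  for (seed in c(101L, 202L, 303L, 404L, 505L)) {
    sim <- simulateDuo(SimConfig(seed = seed), tempfile())
    res <- runDuoPipeline(sim$vcf_P, sim$vcf_R, sim$annotations,
                          sim$panel)
    exp <- expectedCounts(sim$truth)
    expect_equal(as.data.frame(levelCounts(res$audit_P)), exp$audit_P,
                 info = seed)
    expect_equal(as.data.frame(levelCounts(res$audit_R)), exp$audit_R,
                 info = seed)
    a <- assignments(res$assignment)
    e <- exp$categories
    expect_equal(a[order(a$key), "category"], e[order(e$key), "category"],
                 info = seed)
    expect_equal(res$counts, exp$counts, info = seed)
  }
})

test_that("inconsistent simulation configs are rejected", {
  expect_error(SimConfig(n_trunk = 5L, clone_vaf_centers_P = numeric(0)),
               "centers")
  expect_error(SimConfig(n_rescue_trunk = 3L, n_trunk = 2L))
  expect_error(SimConfig(panel_fraction = 1.5))
})
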