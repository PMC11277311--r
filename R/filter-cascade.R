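## The three algorithmic filter levels plus the level-4 review report.
## Each level is a per-record conjunction of predicates; the audit records
## the FIRST failed rule per removed variant, in the fixed order below, so
## audits are deterministic and order-independent within a level.

.LEVEL1_RULES <- c("caller_flag", "depth", "vaf", "alt_reads",
                   "pop_af_1kg", "pop_af_gnomad", "pop_maf_esp",
                   "dbsnp_common")
.LEVEL2_RULES <- c("ontology", "prediction", "clinical_class", "effect",
                   "cosmic")
.LEVEL3_RULES <- c("panel", "gene_role")

#' Construct a filter-cascade configuration
#'
#' All arguments default to the strict FFPE exome triage settings (see
#' \code{\linkS4class{FilterConfig}}). Boundary behavior: the depth, VAF
#' and alternate-read thresholds are inclusive retentions (a record at
#' DP = 50, VAF = 0.15, alt = 20 passes); the population-frequency
#' thresholds are removal-at-or-above (a record at gnomAD AF = 0.02 is
#' removed), and missing frequencies are retained.
#'
#' @param min_depth,min_vaf,min_alt_reads level-1 evidence thresholds.
#' @param max_af_1kg,max_af_gnomad,max_maf_esp population-frequency removal
#'   thresholds (remove at >= threshold; missing retained).
#' @param exclude_dbsnp_common remove common-polymorphism members.
#' @param excluded_ontologies,min_damaging_votes,excluded_clinical_classes,retained_effects,require_cosmic level-2 settings.
#' @param retained_gene_roles level-3 cancer-gene roles kept.
#' @param excluded_caller_flags upstream hard-filter labels removed at
#'   level 1 (caller-dialect specific, hence configurable).
#' @return a \code{FilterConfig}.
#' @export
FilterConfig <- function(min_depth = 50L, min_vaf = 0.15,
                         min_alt_reads = 20L, max_af_1kg = 0.02,
                         max_af_gnomad = 0.02, max_maf_esp = 0.05,
                         exclude_dbsnp_common = TRUE,
                         excluded_ontologies = c("initiator_codon",
                                                 "intragenic", "intron",
                                                 "synonymous"),
                         min_damaging_votes = 1L,
                         excluded_clinical_classes = c("benign",
                                                       "likely_benign",
                                                       "vus_weak_benign"),
                         retained_effects = c("LoF", "missense", "other",
                                              "unknown"),
                         require_cosmic = TRUE,
                         retained_gene_roles = c("oncogene",
                                                 "tumor_suppressor",
                                                 "fusion"),
                         excluded_caller_flags = c("strand_bias",
                                                   "fragment")) {
  new("FilterConfig",
      min_depth = as.integer(min_depth), min_vaf = min_vaf,
      min_alt_reads = as.integer(min_alt_reads), max_af_1kg = max_af_1kg,
      max_af_gnomad = max_af_gnomad, max_maf_esp = max_maf_esp,
      exclude_dbsnp_common = exclude_dbsnp_common,
      excluded_ontologies = excluded_ontologies,
      min_damaging_votes = as.integer(min_damaging_votes),
      excluded_clinical_classes = excluded_clinical_classes,
      retained_effects = retained_effects, require_cosmic = require_cosmic,
      retained_gene_roles = retained_gene_roles,
      excluded_caller_flags = excluded_caller_flags)
}

#' Serialize / load a filter configuration
#'
#' Flat key:value YAML; \code{readFilterConfig(writeFilterConfig(cfg, f))}
#' reproduces \code{cfg} exactly, so cascade runs are config-round-trip
#' stable.
#'
#' @param config a \code{FilterConfig}.
#' @param path file path.
#' @return \code{writeFilterConfig}: \code{path}, invisibly;
#'   \code{readFilterConfig}: a \code{FilterConfig}.
#' @export
writeFilterConfig <- function(config, path) {
  slots <- slotNames("FilterConfig")
  vals <- lapply(slots, function(s) slot(config, s))
  names(vals) <- slots
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname writeFilterConfig
#' @export
readFilterConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(FilterConfig, vals)
}

#' Count damaging in-silico predictor votes
#'
#' Number of the six predictors (SIFT, PolyPhen2-HVAR, MutationTaster,
#' MutationAssessor, FATHMM, FATHMM-MKL) with a \code{damaging} verdict;
#' missing verdicts contribute 0.
#'
#' @param bundle data.frame with the six predictor columns (e.g. a
#'   \code{variantTable}).
#' @return integer vector, one count per row.
#' @export
countDamagingVotes <- function(bundle) {
  if (nrow(bundle) == 0L) return(integer(0))
  votes <- vapply(.PREDICTORS, function(p) {
    v <- bundle[[p]]
    !is.na(v) & v == "damaging"
  }, logical(nrow(bundle)))
  if (nrow(bundle) == 1L) votes <- matrix(votes, nrow = 1L)
  as.integer(rowSums(votes))
}

## split comma-joined flag strings into a list of flag vectors
.flagList <- function(flags) {
  out <- strsplit(flags, ",", fixed = TRUE)
  lapply(out, function(f) f[nzchar(f)])
}

## shared machinery: fails = named list (rule -> logical fail vector, in
## rule order); returns passing rows + removed fragment with first-fail
.runLevel <- function(records, level, fails) {
  v <- variantTable(records)
  reason <- rep(NA_character_, nrow(v))
  for (rule in names(fails)) {
    hit <- fails[[rule]] & is.na(reason)
    reason[hit] <- rule
  }
  removed_idx <- which(!is.na(reason))
  removed <- data.frame(key = makeVariantKey(v)[removed_idx],
                        level = rep(level, length(removed_idx)),
                        reason = reason[removed_idx],
                        stringsAsFactors = FALSE)
  passing <- VariantSet(sampleId(records),
                        v[is.na(reason), , drop = FALSE],
                        annotated = isAnnotated(records))
  list(passing = passing, removed = removed,
       entering = nrow(v), n_passing = nVariants(passing))
}

#' Level 1: technical-quality and polymorphism filter
#'
#' Removes caller-flagged calls (strand-bias / fragment hard filters),
#' low-evidence calls (DP, VAF, alternate reads below the inclusive
#' thresholds), common population variants (1kG / gnomAD exome allele
#' frequency or ESP minor allele frequency at or above the removal
#' thresholds; missing values retained) and common-polymorphism members.
#'
#' @param records an annotated \code{VariantSet}.
#' @param config a \code{FilterConfig}.
#' @return list with elements \code{passing} (a \code{VariantSet}),
#'   \code{removed} (data.frame key/level/reason), \code{entering},
#'   \code{n_passing}.
#' @export
level1QualityFilter <- function(records, config = FilterConfig()) {
  stopifnot(isAnnotated(records))
  v <- variantTable(records)
  flagged <- vapply(.flagList(v$caller_flags), function(f)
    length(intersect(f, config@excluded_caller_flags)) > 0L, logical(1L))
  if (nrow(v) == 0L) flagged <- logical(0)
  fails <- list(
    caller_flag = flagged,
    depth = v$total_depth < config@min_depth,
    vaf = v$vaf < config@min_vaf,
    alt_reads = v$alt_depth < config@min_alt_reads,
    pop_af_1kg = !is.na(v$af_1kg) & v$af_1kg >= config@max_af_1kg,
    pop_af_gnomad = !is.na(v$af_gnomad_exome) &
      v$af_gnomad_exome >= config@max_af_gnomad,
    pop_maf_esp = !is.na(v$maf_esp) & v$maf_esp >= config@max_maf_esp,
    dbsnp_common = config@exclude_dbsnp_common & v$dbsnp_common)
  .runLevel(records, 1L, fails[.LEVEL1_RULES])
}

#' Level 2: biological-relevance filter
#'
#' Removes excluded sequence ontologies (initiator codon, intragenic,
#' intron, synonymous by default), variants with fewer than
#' \code{min_damaging_votes} damaging in-silico verdicts, clinically
#' non-significant classes (benign, likely benign, weak-benign VUS),
#' non-retained effect classes, and — when \code{require_cosmic} — variants
#' without any cancer-catalogue record.
#'
#' @inheritParams level1QualityFilter
#' @return as \code{\link{level1QualityFilter}}.
#' @export
level2RelevanceFilter <- function(records, config = FilterConfig()) {
  stopifnot(isAnnotated(records))
  v <- variantTable(records)
  fails <- list(
    ontology = v$seq_ontology %in% config@excluded_ontologies,
    prediction = countDamagingVotes(v) < config@min_damaging_votes,
    clinical_class = !is.na(v$clinical_class) &
      v$clinical_class %in% config@excluded_clinical_classes,
    effect = !(v$effect %in% config@retained_effects),
    cosmic = config@require_cosmic & !nzchar(v$cosmic_ids))
  .runLevel(records, 2L, fails[.LEVEL2_RULES])
}

#' Level 3: gene-panel and cancer-gene-role filter
#'
#' Keeps variants in panel genes whose catalogued cancer-gene role is one
#' of the retained roles (oncogene, tumor suppressor, fusion by default).
#' Gene symbols are compared case-insensitively.
#'
#' @inheritParams level1QualityFilter
#' @param panel a \code{GenePanel}.
#' @return as \code{\link{level1QualityFilter}}.
#' @export
level3PanelFilter <- function(records, panel, config = FilterConfig()) {
  stopifnot(isAnnotated(records), is(panel, "GenePanel"))
  v <- variantTable(records)
  fails <- list(
    panel = !(toupper(trimws(v$gene)) %in% panelSymbols(panel)),
    gene_role = !(v$gene_role %in% config@retained_gene_roles))
  .runLevel(records, 3L, fails[.LEVEL3_RULES])
}

#' Apply the filter cascade
#'
#' Runs the requested levels in order 1 to 3, threading each level's
#' passing set into the next, and assembles the complete
#' \code{\linkS4class{FilterAudit}}: entering/passing counts per level and
#' one first-fail reason per removed variant. \code{levels = 1} reproduces
#' the level-1-only variant set used for the tumor-mutation-rate and VAF
#' clonality metrics.
#'
#' @param records an annotated \code{VariantSet}.
#' @param panel a \code{GenePanel} (required when level 3 is run).
#' @param config a \code{FilterConfig}.
#' @param levels integer subset of 1:3 (a prefix; default all three).
#' @return list with \code{passing} (a \code{VariantSet}) and \code{audit}
#'   (a \code{FilterAudit}).
#' @export
applyCascade <- function(records, panel = NULL, config = FilterConfig(),
                         levels = 1:3) {
  levels <- as.integer(levels)
  stopifnot(all(levels %in% 1:3),
            identical(levels, seq_len(length(levels))))
  current <- records
  lvl_rows <- list()
  removed <- list()
  rule_order <- character(0)
  for (lvl in levels) {
    res <- switch(lvl,
                  level1QualityFilter(current, config),
                  level2RelevanceFilter(current, config),
                  {
                    if (is.null(panel))
                      stop("a GenePanel is required for level 3")
                    level3PanelFilter(current, panel, config)
                  })
    lvl_rows[[lvl]] <- data.frame(level = lvl, entering = res$entering,
                                  passing = res$n_passing)
    removed[[lvl]] <- res$removed
    rule_order <- c(rule_order,
                    switch(lvl, .LEVEL1_RULES, .LEVEL2_RULES, .LEVEL3_RULES))
    current <- res$passing
  }
  audit <- new("FilterAudit",
               levels = do.call(rbind, lvl_rows),
               removed = do.call(rbind, removed),
               ruleOrder = rule_order)
  list(passing = current, audit = audit)
}

#' Write the filter audit
#'
#' Emits the audit as two artifacts: a TSV of per-variant first-fail
#' reasons and a human-readable per-level count log.
#'
#' @param audit a \code{FilterAudit}.
#' @param tsv_path path for the removed-variant TSV.
#' @param log_path optional path for the count log (skipped when NULL).
#' @return \code{tsv_path}, invisibly.
#' @export
writeFilterAudit <- function(audit, tsv_path, log_path = NULL) {
  utils::write.table(removedVariants(audit), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(log_path)) {
    lv <- levelCounts(audit)
    lines <- sprintf("level %d: %d entering, %d passing, %d removed",
                     lv$level, lv$entering, lv$passing,
                     lv$entering - lv$passing)
    writeLines(lines, log_path)
  }
  invisible(tsv_path)
}

#' Write the level-4 manual-review report
#'
#' The fourth filter level is expert curation, not an algorithm: this emits
#' the cascade survivors as a ranked review TSV, sorted by oncogenicity
#' score then catalogue recurrence count, both descending, for a human
#' reviewer.
#'
#' @param records cascade-passing annotated \code{VariantSet}.
#' @param calls data.frame of oncogenicity calls from
#'   \code{\link{scoreVariants}} (one row per record).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeReviewReport <- function(records, calls, path) {
  v <- variantTable(records)
  stopifnot(nrow(calls) == nrow(v))
  out <- cbind(data.frame(sample_id = rep(sampleId(records), nrow(v)),
                          key = makeVariantKey(v)), v, calls)
  out <- out[order(-calls$score, -v$cosmic_count), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
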