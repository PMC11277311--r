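## Central S4 classes. All tabular payloads are plain data.frames so every
## object flattens losslessly to the TSV interchange formats.

## enum vocabularies shared by readers, validity methods and the simulator
.SEQ_ONTOLOGIES <- c("missense", "frameshift", "splice_variant", "stop_gained",
                     "initiator_codon", "intragenic", "intron", "synonymous",
                     "other")
.EFFECTS <- c("LoF", "missense", "other", "unknown", "none")
.CLINICAL_CLASSES <- c("benign", "likely_benign", "vus_weak_benign", "other")
.GENE_ROLES <- c("oncogene", "tumor_suppressor", "fusion", "none")
.PREDICTORS <- c("sift", "polyphen2_hvar", "mutation_taster",
                 "mutation_assessor", "fathmm", "fathmm_mkl")
.PREDICTOR_VERDICTS <- c("damaging", "tolerated")

## column layout of the variants data.frame inside a VariantSet
.CORE_COLS <- c("chrom", "pos", "ref", "alt", "total_depth", "alt_depth",
                "vaf", "caller_flags")
.ANNOT_COLS <- c("af_1kg", "af_gnomad_exome", "maf_esp", "dbsnp_common",
                 "seq_ontology", "effect", .PREDICTORS, "clinical_class",
                 "cosmic_ids", "cosmic_count", "gene", "gene_role",
                 "hgvs_c", "hgvs_p")

#' Set of somatic variant calls for one sample
#'
#' A \code{VariantSet} holds one sample's somatic variant calls as a flat
#' data.frame, one row per (site, alternate allele). Multiallelic sites are
#' split on read, so \code{alt} is always a single allele. The variant allele
#' frequency (\code{vaf}) is always recomputed from the allelic depths
#' (\code{alt_depth / total_depth}) and never trusted from the input; the
#' validity method enforces agreement to within 1e-9. Non-PASS FILTER labels
#' from the upstream caller are kept in \code{caller_flags}
#' (comma-separated, empty string when PASS).
#'
#' After \code{\link{attachAnnotations}} the table additionally carries the
#' annotation bundle columns (population allele frequencies with \code{NA}
#' meaning missing, sequence ontology, predicted effect, six in-silico
#' predictor verdicts, clinical class, cancer-catalogue IDs and sample count,
#' gene symbol and cancer-gene role, HGVS strings) and \code{annotated()} is
#' \code{TRUE}.
#'
#' @slot sampleId single sample identifier.
#' @slot variants data.frame, one row per alternate allele.
#' @slot annotated logical; \code{TRUE} once annotation columns are present.
#' @seealso \code{\link{readVcfVariants}}, \code{\link{attachAnnotations}},
#'   \code{\link{applyCascade}}
#' @export
setClass("VariantSet",
         representation(sampleId = "character",
                        variants = "data.frame",
                        annotated = "logical"),
         prototype(sampleId = NA_character_,
                   variants = data.frame(),
                   annotated = FALSE))

setValidity("VariantSet", function(object) {
  v <- object@variants
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    return("sampleId must be a single non-NA string")
  missing_core <- setdiff(.CORE_COLS, names(v))
  if (length(missing_core))
    return(paste("missing columns:", paste(missing_core, collapse = ", ")))
  if (nrow(v) == 0L) return(TRUE)
  if (any(grepl(",", v$alt, fixed = TRUE)))
    return("multiallelic alt fields must be split into one row per allele")
  if (any(v$alt_depth < 0L | v$alt_depth > v$total_depth))
    return("alt_depth must satisfy 0 <= alt_depth <= total_depth")
  pos <- v$total_depth > 0L
  if (any(abs(v$vaf[pos] - v$alt_depth[pos] / v$total_depth[pos]) > 1e-9))
    return("vaf must equal alt_depth / total_depth (recomputed) within 1e-9")
  if (object@annotated) {
    missing_ann <- setdiff(.ANNOT_COLS, names(v))
    if (length(missing_ann))
      return(paste("annotated set lacks columns:",
                   paste(missing_ann, collapse = ", ")))
    if (!all(v$seq_ontology %in% .SEQ_ONTOLOGIES))
      return("invalid seq_ontology value")
    if (!all(v$effect %in% .EFFECTS))
      return("invalid effect value")
    if (!all(v$gene_role %in% .GENE_ROLES))
      return("invalid gene_role value")
    if (!all(is.na(v$clinical_class) | v$clinical_class %in% .CLINICAL_CLASSES))
      return("invalid clinical_class value")
    for (p in .PREDICTORS)
      if (!all(is.na(v[[p]]) | v[[p]] %in% .PREDICTOR_VERDICTS))
        return(paste("invalid verdict in predictor column", p))
    if (any(v$cosmic_count < 0L))
      return("cosmic_count must be >= 0")
  }
  TRUE
})

#' Gene panel
#'
#' A named set of gene symbols restricting level-3 filtering, e.g. a
#' glioma-specific panel. Symbols are trimmed, upper-cased and
#' de-duplicated on read, since panels and annotation sources use
#' heterogeneous casing.
#'
#' @slot symbols unique, case-normalized gene symbols.
#' @slot name panel name.
#' @seealso \code{\link{readGenePanel}}
#' @export
setClass("GenePanel",
         representation(symbols = "character", name = "character"))

setValidity("GenePanel", function(object) {
  if (length(object@symbols) == 0L) return("panel must be non-empty")
  if (anyDuplicated(object@symbols)) return("panel symbols must be unique")
  if (!identical(object@symbols, toupper(trimws(object@symbols))))
    return("panel symbols must be case-normalized")
  TRUE
})

#' Filter-cascade configuration
#'
#' Thresholds and category sets for the three algorithmic filter levels.
#' Defaults reproduce the strict FFPE exome triage settings: level 1 removes
#' caller-flagged calls (strand bias / fragment hard filters), applies
#' DP >= 50, VAF >= 15\% and alternate reads >= 20 (all inclusive
#' retentions), removes common polymorphisms (1kG/gnomAD allele frequency
#' >= 2\%, ESP minor allele frequency >= 5\%, dbSNP-common membership;
#' missing frequencies are retained). Level 2 keeps relevant consequences
#' (ontology not in the excluded set, >= 1 damaging in-silico vote, clinical
#' class not benign-like, retained effect class, >= 1 cancer-catalogue
#' record). Level 3 restricts to panel genes with an oncogene / tumor
#' suppressor / fusion role.
#'
#' @export
setClass("FilterConfig",
         representation(min_depth = "integer",
                        min_vaf = "numeric",
                        min_alt_reads = "integer",
                        max_af_1kg = "numeric",
                        max_af_gnomad = "numeric",
                        max_maf_esp = "numeric",
                        exclude_dbsnp_common = "logical",
                        excluded_ontologies = "character",
                        min_damaging_votes = "integer",
                        excluded_clinical_classes = "character",
                        retained_effects = "character",
                        require_cosmic = "logical",
                        retained_gene_roles = "character",
                        excluded_caller_flags = "character"),
         prototype(min_depth = 50L,
                   min_vaf = 0.15,
                   min_alt_reads = 20L,
                   max_af_1kg = 0.02,
                   max_af_gnomad = 0.02,
                   max_maf_esp = 0.05,
                   exclude_dbsnp_common = TRUE,
                   excluded_ontologies = c("initiator_codon", "intragenic",
                                           "intron", "synonymous"),
                   min_damaging_votes = 1L,
                   excluded_clinical_classes = c("benign", "likely_benign",
                                                 "vus_weak_benign"),
                   retained_effects = c("LoF", "missense", "other", "unknown"),
                   require_cosmic = TRUE,
                   retained_gene_roles = c("oncogene", "tumor_suppressor",
                                           "fusion"),
                   excluded_caller_flags = c("strand_bias", "fragment")))

setValidity("FilterConfig", function(object) {
  fr <- c(object@min_vaf, object@max_af_1kg, object@max_af_gnomad,
          object@max_maf_esp)
  if (any(fr < 0 | fr > 1)) return("fraction thresholds must lie in [0, 1]")
  if (object@min_depth < 0L || object@min_alt_reads < 0L ||
      object@min_damaging_votes < 0L)
    return("count thresholds must be non-negative")
  TRUE
})

#' Audit trail of a filter-cascade run
#'
#' Per-level entering/passing counts plus one first-fail reason for every
#' removed variant, recorded in the fixed rule order of the cascade so audits
#' are deterministic. \code{passing} at level k always equals \code{entering}
#' at level k+1.
#'
#' @slot levels data.frame with columns level, entering, passing.
#' @slot removed data.frame with columns key, level, reason.
#' @slot ruleOrder character, applied rule names in order.
#' @export
setClass("FilterAudit",
         representation(levels = "data.frame",
                        removed = "data.frame",
                        ruleOrder = "character"))

setValidity("FilterAudit", function(object) {
  lv <- object@levels
  if (nrow(lv)) {
    if (any(lv$passing > lv$entering))
      return("passing count cannot exceed entering count")
    if (nrow(lv) > 1L &&
        any(lv$entering[-1L] != lv$passing[-nrow(lv)]))
      return("entering(k+1) must equal passing(k)")
    tallies <- table(factor(object@removed$level, levels = lv$level))
    if (any(as.integer(tallies) != lv$entering - lv$passing))
      return("removed-variant tally must equal entering - passing per level")
  }
  TRUE
})

#' Cross-sample rescue configuration
#'
#' A variant passing the cascade in one member of a pair is searched for in
#' the partner sample; an allele-exact partner record with at least
#' \code{min_partner_alt_reads} alternate reads and VAF >=
#' \code{min_partner_vaf} rescues the variant into the shared category.
#' \code{search_raw} selects the partner's pre-filter calls (default) rather
#' than its level-1 survivors.
#'
#' @export
setClass("RescueConfig",
         representation(min_partner_alt_reads = "integer",
                        min_partner_vaf = "numeric",
                        search_raw = "logical"),
         prototype(min_partner_alt_reads = 5L,
                   min_partner_vaf = 0.05,
                   search_raw = TRUE))

setValidity("RescueConfig", function(object) {
  if (object@min_partner_alt_reads < 0L || object@min_partner_vaf < 0)
    return("rescue thresholds must be non-negative")
  TRUE
})

#' Duo categorization of a sample pair's variants
#'
#' Partition of the union of both samples' cascade-passing variants into
#' P_ONLY (primary-exclusive), R_ONLY (recurrent-exclusive) and SHARED.
#' A shared variant is counted once per pair. \code{rescueEvents} records
#' variants that passed in one sample only but were recovered in the
#' partner's calls.
#'
#' @slot pairId pair identifier.
#' @slot assignments data.frame with columns key, category.
#' @slot rescueEvents data.frame with columns key, rescued_in,
#'   partner_alt_depth, partner_vaf.
#' @export
setClass("DuoAssignment",
         representation(pairId = "character",
                        assignments = "data.frame",
                        rescueEvents = "data.frame"))

setValidity("DuoAssignment", function(object) {
  a <- object@assignments
  if (nrow(a)) {
    if (!all(a$category %in% c("P_ONLY", "R_ONLY", "SHARED")))
      return("category must be P_ONLY, R_ONLY or SHARED")
    if (anyDuplicated(a$key))
      return("assignment keys must be unique (one category per variant)")
  }
  TRUE
})

#' Points-based oncogenicity rubric
#'
#' An ordered list of rules, each a named predicate over an annotated
#' variant row worth an integer number of points (negative points allowed),
#' plus the two class thresholds: score >= \code{oncogenic_min} is
#' Oncogenic, \code{likely_min} <= score < \code{oncogenic_min} is Likely
#' oncogenic, anything below is VUS. \code{\link{defaultRubric}} builds the
#' shipped rubric.
#'
#' @slot rules list of rules; each rule is a list(name, points, predicate).
#' @slot oncogenic_min minimum score for the Oncogenic class (default 5).
#' @slot likely_min minimum score for the Likely-oncogenic class (default 3).
#' @export
setClass("Rubric",
         representation(rules = "list",
                        oncogenic_min = "integer",
                        likely_min = "integer"),
         prototype(rules = list(), oncogenic_min = 5L, likely_min = 3L))

setValidity("Rubric", function(object) {
  if (!(object@oncogenic_min > object@likely_min && object@likely_min >= 1L))
    return("thresholds must satisfy oncogenic_min > likely_min >= 1")
  for (r in object@rules) {
    if (!all(c("name", "points", "predicate") %in% names(r)))
      return("each rule needs name, points and predicate")
    if (!is.function(r$predicate)) return("rule predicate must be a function")
  }
  TRUE
})

#' One-dimensional Gaussian-mixture fit of a VAF distribution
#'
#' Result of \code{\link{fitVafMixture}}: the selected number of clonal
#' components with their weights, means and variances, the per-candidate
#' model-selection table (equal-variance and free-variance families, scored
#' by BIC), and convergence information.
#'
#' @slot nComponents selected number of components.
#' @slot weights,means,variances parameters of the selected model.
#' @slot family variance family of the selected model ("E" equal, "V" free).
#' @slot candidates data.frame with one row per (k, family) candidate:
#'   loglik, bic, converged, iterations.
#' @slot converged convergence flag of the selected fit.
#' @slot seed integer seed recorded with the fit.
#' @export
setClass("MixtureFit",
         representation(nComponents = "integer",
                        weights = "numeric",
                        means = "numeric",
                        variances = "numeric",
                        family = "character",
                        candidates = "data.frame",
                        converged = "logical",
                        seed = "integer"))

setValidity("MixtureFit", function(object) {
  if (object@nComponents < 1L) return("nComponents must be >= 1")
  if (abs(sum(object@weights) - 1) > 1e-9)
    return("component weights must sum to 1 within 1e-9")
  if (any(object@means < 0 | object@means > 1))
    return("component means must lie in [0, 1]")
  if (nrow(object@candidates)) {
    best <- min(object@candidates$bic)
    sel <- object@candidates[object@candidates$k == object@nComponents &
                             object@candidates$family == object@family, ]
    if (nrow(sel) == 1L && sel$bic > best + 1e-6)
      return("selected model must minimize BIC among candidates")
  }
  TRUE
})

#' Longitudinal metrics for one tumor sample
#'
#' Tumor mutation rate (total level-1-passing variants, per megabase of the
#' capture, and log10 thereof), MATH intra-tumor-heterogeneity score, and
#' the VAF mixture fit. \code{per_mb} is exactly
#' \code{total_mutations / capture_mb}; \code{log10_per_mb} and
#' \code{math_score} are \code{NA} when undefined (zero mutations; zero
#' median VAF).
#'
#' @export
setClass("SampleMetrics",
         representation(sampleId = "character",
                        total_mutations = "integer",
                        capture_mb = "numeric",
                        per_mb = "numeric",
                        log10_per_mb = "numeric",
                        math_score = "numeric",
                        mixture = "ANY"))

setValidity("SampleMetrics", function(object) {
  if (object@capture_mb <= 0) return("capture_mb must be positive")
  if (abs(object@per_mb - object@total_mutations / object@capture_mb) > 1e-9)
    return("per_mb must equal total_mutations / capture_mb")
  if (!is.na(object@math_score) && object@math_score < 0)
    return("math_score must be >= 0 when defined")
  TRUE
})

#' Synthetic paired-cohort simulation configuration
#'
#' Parameters of \code{\link{simulateDuo}}. Defaults emulate the paired
#' FFPE glioblastoma exome setting: a 42 Mb capture, mean read depth 180,
#' trunk (shared) and private true variants drawn from clone-specific VAF
#' centers with standard deviation \code{clone_sd}, low-VAF caller-flagged
#' FFPE-style C>T artifacts, and high-population-frequency common
#' polymorphisms. \code{n_rescue_trunk} trunk variants are degraded below
#' the level-1 VAF threshold in the recurrent sample while staying above the
#' rescue floor, exercising the cross-sample rescue path.
#'
#' @export
setClass("SimConfig",
         representation(seed = "integer",
                        capture_mb = "numeric",
                        n_trunk = "integer",
                        n_private_P = "integer",
                        n_private_R = "integer",
                        clone_vaf_centers_P = "numeric",
                        clone_vaf_centers_R = "numeric",
                        clone_sd = "numeric",
                        n_artifacts_P = "integer",
                        n_artifacts_R = "integer",
                        artifact_vaf_range = "numeric",
                        n_polymorphisms = "integer",
                        depth_mean = "integer",
                        panel_fraction = "numeric",
                        n_rescue_trunk = "integer",
                        driver_catalogue = "data.frame"),
         prototype(seed = 1L,
                   capture_mb = 42,
                   n_trunk = 8L,
                   n_private_P = 20L,
                   n_private_R = 30L,
                   clone_vaf_centers_P = c(0.25, 0.45),
                   clone_vaf_centers_R = c(0.22, 0.40),
                   clone_sd = 0.03,
                   n_artifacts_P = 15L,
                   n_artifacts_R = 15L,
                   artifact_vaf_range = c(0.01, 0.10),
                   n_polymorphisms = 10L,
                   depth_mean = 180L,
                   panel_fraction = 0.6,
                   n_rescue_trunk = 1L,
                   driver_catalogue = data.frame()))

setValidity("SimConfig", function(object) {
  counts <- c(object@n_trunk, object@n_private_P, object@n_private_R,
              object@n_artifacts_P, object@n_artifacts_R,
              object@n_polymorphisms, object@n_rescue_trunk)
  if (any(counts < 0L)) return("all counts must be >= 0")
  ctr <- c(object@clone_vaf_centers_P, object@clone_vaf_centers_R)
  if (length(ctr) && any(ctr <= 0 | ctr >= 1))
    return("clone VAF centers must lie in (0, 1)")
  if (object@n_trunk > 0L &&
      (length(object@clone_vaf_centers_P) == 0L ||
       length(object@clone_vaf_centers_R) == 0L))
    return("clone VAF centers must be non-empty when true variants are planted")
  if (object@n_rescue_trunk > object@n_trunk)
    return("n_rescue_trunk cannot exceed n_trunk")
  if (length(object@artifact_vaf_range) != 2L ||
      diff(object@artifact_vaf_range) < 0)
    return("artifact_vaf_range must be an increasing pair")
  if (object@panel_fraction < 0 || object@panel_fraction > 1)
    return("panel_fraction must lie in [0, 1]")
  if (object@capture_mb <= 0 || object@depth_mean <= 0L)
    return("capture_mb and depth_mean must be positive")
  TRUE
})

#' Cohort-level summary
#'
#' Per-pair oncogenicity-category count rows (SUM/O/LO/VUS for each of the
#' primary-only, recurrent-only and shared categories) with a half-up
#' rounded Mean row, gene-by-category and gene-by-ontology matrices over
#' oncogenic/likely-oncogenic variants, per-sample tumor-mutation-rate rows
#' and per-pair heterogeneity trends.
#'
#' @export
setClass("CohortSummary",
         representation(pairCounts = "data.frame",
                        meanRow = "data.frame",
                        geneByCategory = "matrix",
                        geneByOntology = "matrix",
                        tmrRows = "data.frame",
                        trends = "data.frame"))
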