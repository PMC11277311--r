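## End-to-end convenience wrapper: one matched pair from files to
## assignment, calls, counts and metrics. The command-line entry point and
## the cohort summary build on this.

#' Run the full triage pipeline on one duo
#'
#' Reads both samples' VCFs and the shared annotation table, attaches
#' annotations, runs the three-level filter cascade per sample, categorizes
#' the union of survivors into primary-only / recurrent-only / shared with
#' cross-sample rescue, scores oncogenicity, and computes the per-sample
#' longitudinal metrics on the level-1-passing sets.
#'
#' @param vcf_P,vcf_R paths to the primary and recurrent sample VCFs.
#' @param annotations_path path to the annotation TSV.
#' @param panel_path path to the gene panel file.
#' @param pair_id pair identifier.
#' @param sample_P,sample_R sample identifiers (defaults derived from
#'   \code{pair_id}).
#' @param config a \code{FilterConfig}.
#' @param rescue_config a \code{RescueConfig}.
#' @param rubric a \code{Rubric}.
#' @param capture_mb capture size in megabases for the mutation rate.
#' @param seed seed recorded with the mixture fits.
#' @return list with \code{assignment}, \code{calls}, \code{counts},
#'   \code{annotations} (keyed), \code{metrics_P}, \code{metrics_R},
#'   \code{passing_P}, \code{passing_R}, \code{audit_P}, \code{audit_R}.
#' @export
runDuoPipeline <- function(vcf_P, vcf_R, annotations_path, panel_path,
                           pair_id = "duo1",
                           sample_P = paste0(pair_id, "_P"),
                           sample_R = paste0(pair_id, "_R"),
                           config = FilterConfig(),
                           rescue_config = RescueConfig(),
                           rubric = defaultRubric(), capture_mb = 42,
                           seed = 1L) {
  bundles <- readAnnotations(annotations_path)
  panel <- readGenePanel(panel_path)
  raw_P <- attachAnnotations(readVcfVariants(vcf_P, sample_P), bundles)
  raw_R <- attachAnnotations(readVcfVariants(vcf_R, sample_R), bundles)

  cas_P <- applyCascade(raw_P, panel, config)
  cas_R <- applyCascade(raw_R, panel, config)
  lvl1_P <- applyCascade(raw_P, panel, config, levels = 1L)$passing
  lvl1_R <- applyCascade(raw_R, panel, config, levels = 1L)$passing

  assignment <- categorizeDuo(cas_P$passing, cas_R$passing, raw_P, raw_R,
                              rescue_config, pair_id = pair_id)

  union_tab <- rbind(variantTable(cas_P$passing),
                     variantTable(cas_R$passing))
  union_tab <- union_tab[!duplicated(makeVariantKey(union_tab)), ,
                         drop = FALSE]
  calls <- scoreVariants(union_tab, rubric)
  calls$cosmic_count <- union_tab$cosmic_count
  calls$gene <- union_tab$gene

  list(assignment = assignment, calls = calls,
       counts = countCategories(assignment, calls),
       annotations = bundles,
       metrics_P = sampleMetrics(lvl1_P, capture_mb, seed = seed),
       metrics_R = sampleMetrics(lvl1_R, capture_mb, seed = seed),
       passing_P = cas_P$passing, passing_R = cas_R$passing,
       audit_P = cas_P$audit, audit_R = cas_R$audit)
}
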