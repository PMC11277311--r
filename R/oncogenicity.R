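## Points-based oncogenicity scoring. The score is the sum of points over
## fired rubric rules; class thresholds are score >= 5 Oncogenic, 3-4
## Likely oncogenic, <= 2 (including negatives) VUS. The shipped default
## rubric follows published points-based oncogenicity SOPs: recurrence
## tiers in the cancer-mutation catalogue, loss-of-function in a tumor
## suppressor, damaging-vote-supported missense, splice disruption,
## recurrent oncogene hits, with a penalty for presence in population
## frequency databases. Additivity of evidence is a modeling choice of this
## package; precomputed scores can be supplied instead via
## scoreFromColumn().

#' The default oncogenicity rubric
#'
#' Rules, in order (highest applicable catalogue tier only):
#' \itemize{
#'   \item \code{catalogue_high}: catalogue sample count >= 50, +4
#'   \item \code{catalogue_mid}: count >= 10 (and < 50), +2
#'   \item \code{catalogue_low}: count >= 1 (and < 10), +1
#'   \item \code{lof_tumor_suppressor}: LoF effect in a tumor-suppressor
#'     gene, +4
#'   \item \code{damaging_missense}: missense effect with >= 3 damaging
#'     predictor votes, +2
#'   \item \code{splice_disruption}: splice-variant ontology, +2
#'   \item \code{recurrent_oncogene}: oncogene with catalogue count >= 10,
#'     +2
#'   \item \code{population_presence}: any population allele frequency
#'     recorded (not missing), -4
#' }
#'
#' @param oncogenic_min,likely_min class thresholds (defaults 5 and 3).
#' @return a \code{\linkS4class{Rubric}}.
#' @export
defaultRubric <- function(oncogenic_min = 5L, likely_min = 3L) {
  rules <- list(
    list(name = "catalogue_high", points = 4L,
         predicate = function(v) v$cosmic_count >= 50L),
    list(name = "catalogue_mid", points = 2L,
         predicate = function(v) v$cosmic_count >= 10L & v$cosmic_count < 50L),
    list(name = "catalogue_low", points = 1L,
         predicate = function(v) v$cosmic_count >= 1L & v$cosmic_count < 10L),
    list(name = "lof_tumor_suppressor", points = 4L,
         predicate = function(v) v$effect == "LoF" &
           v$gene_role == "tumor_suppressor"),
    list(name = "damaging_missense", points = 2L,
         predicate = function(v) v$effect == "missense" &
           countDamagingVotes(v) >= 3L),
    list(name = "splice_disruption", points = 2L,
         predicate = function(v) v$seq_ontology == "splice_variant"),
    list(name = "recurrent_oncogene", points = 2L,
         predicate = function(v) v$gene_role == "oncogene" &
           v$cosmic_count >= 10L),
    list(name = "population_presence", points = -4L,
         predicate = function(v) !is.na(v$af_1kg) |
           !is.na(v$af_gnomad_exome) | !is.na(v$maf_esp)))
  new("Rubric", rules = rules, oncogenic_min = as.integer(oncogenic_min),
      likely_min = as.integer(likely_min))
}

#' Classify integer oncogenicity scores
#'
#' ONCOGENIC iff score >= \code{oncogenic_min}; LIKELY_ONCOGENIC iff
#' \code{likely_min} <= score < \code{oncogenic_min}; VUS otherwise
#' (including all negative scores). Total and deterministic over the
#' integers.
#'
#' @param score integer vector of scores.
#' @param oncogenic_min,likely_min class thresholds (defaults 5 and 3).
#' @return character vector of classes.
#' @export
classifyScore <- function(score, oncogenic_min = 5L, likely_min = 3L) {
  stopifnot(oncogenic_min > likely_min, likely_min >= 1L)
  ifelse(score >= oncogenic_min, "ONCOGENIC",
         ifelse(score >= likely_min, "LIKELY_ONCOGENIC", "VUS"))
}

#' Score annotated variants with a rubric
#'
#' For each record the score is the sum of points of all rules whose
#' predicate holds; \code{evidence} lists the fired rules in rubric order.
#' Scoring is pure: the same record always yields the same call.
#'
#' @param records an annotated \code{VariantSet} (or its
#'   \code{variantTable} data.frame).
#' @param rubric a \code{Rubric}; default \code{\link{defaultRubric}()}.
#' @return data.frame with columns \code{key}, \code{score},
#'   \code{evidence} (comma-joined rule names) and \code{oclass}.
#' @export
scoreVariants <- function(records, rubric = defaultRubric()) {
  v <- if (is(records, "VariantSet")) variantTable(records) else records
  n <- nrow(v)
  score <- integer(n)
  evidence <- rep("", n)
  if (n > 0L) for (r in rubric@rules) {
    hit <- r$predicate(v)
    hit[is.na(hit)] <- FALSE
    score <- score + ifelse(hit, r$points, 0L)
    evidence <- ifelse(hit,
                       ifelse(nzchar(evidence),
                              paste(evidence, r$name, sep = ","), r$name),
                       evidence)
  }
  data.frame(key = if (is(records, "VariantSet")) variantKeys(records)
                   else makeVariantKey(v),
             score = as.integer(score), evidence = evidence,
             oclass = classifyScore(score, rubric@oncogenic_min,
                                    rubric@likely_min),
             stringsAsFactors = FALSE)
}

#' Use precomputed scores instead of the rubric
#'
#' Alternative scoring path for annotation tables that already carry an
#' external classifier's integer score: classes are assigned from the
#' given column under the same thresholds.
#'
#' @param records annotated \code{VariantSet} or data.frame.
#' @param score integer vector of precomputed scores, one per record.
#' @param oncogenic_min,likely_min class thresholds.
#' @return data.frame as \code{\link{scoreVariants}} (evidence column
#'   \code{"precomputed"}).
#' @export
scoreFromColumn <- function(records, score, oncogenic_min = 5L,
                            likely_min = 3L) {
  v <- if (is(records, "VariantSet")) variantTable(records) else records
  stopifnot(length(score) == nrow(v))
  data.frame(key = makeVariantKey(v), score = as.integer(score),
             evidence = rep("precomputed", nrow(v)),
             oclass = classifyScore(as.integer(score), oncogenic_min,
                                    likely_min),
             stringsAsFactors = FALSE)
}

#' Serialize / load a rubric configuration
#'
#' The parameterised default rubric round-trips through flat YAML (rule
#' names, points, thresholds). Custom predicate functions are programmatic
#' only and are not serialized; loading reconstructs the default rule
#' predicates with the stored points and thresholds.
#'
#' @param rubric a \code{Rubric} built by \code{\link{defaultRubric}}.
#' @param path file path.
#' @return \code{writeRubric}: \code{path}, invisibly; \code{readRubric}:
#'   a \code{Rubric}.
#' @export
writeRubric <- function(rubric, path) {
  vals <- list(oncogenic_min = rubric@oncogenic_min,
               likely_min = rubric@likely_min,
               points = stats::setNames(
                 lapply(rubric@rules, function(r) r$points),
                 vapply(rubric@rules, function(r) r$name, character(1L))))
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname writeRubric
#' @export
readRubric <- function(path) {
  vals <- yaml::read_yaml(path)
  rubric <- defaultRubric(vals$oncogenic_min, vals$likely_min)
  rubric@rules <- lapply(rubric@rules, function(r) {
    if (!is.null(vals$points[[r$name]]))
      r$points <- as.integer(vals$points[[r$name]])
    r
  })
  validObject(rubric)
  rubric
}
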