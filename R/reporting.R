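## Cohort-level summaries (category-count table with Mean row, gene-level
## matrices over oncogenic/likely-oncogenic variants, TMR rows,
## heterogeneity trends) and the bundled reference-cohort tables.

#' Mean row of a per-pair category-count table
#'
#' The oncogenic / likely-oncogenic / VUS class columns are averaged over
#' the pair rows and rounded half-up to integers; each SUM column is
#' presented as the sum of its three rounded class means, so the Mean row
#' preserves the SUM = O + LO + VUS identity that holds in every pair row
#' (the convention of published cohort count tables; note it can differ by
#' one from directly rounding the SUM mean). Raw means of all 12 columns
#' are attached as the \code{"raw"} attribute.
#'
#' @param pair_counts data.frame of per-pair rows with the 12 count
#'   columns (P_SUM..S_VUS) as produced by \code{\link{countCategories}}.
#' @return one-row data.frame of rounded means.
#' @export
summarizeCounts <- function(pair_counts) {
  cols <- c("P_SUM", "P_O", "P_LO", "P_VUS", "R_SUM", "R_O", "R_LO",
            "R_VUS", "S_SUM", "S_O", "S_LO", "S_VUS")
  stopifnot(all(cols %in% names(pair_counts)))
  raw <- vapply(pair_counts[cols], mean, numeric(1L))
  rounded <- roundHalfUp(raw, 0)
  for (pre in c("P", "R", "S"))
    rounded[paste0(pre, "_SUM")] <-
      sum(rounded[paste0(pre, c("_O", "_LO", "_VUS"))])
  out <- as.data.frame(as.list(rounded))
  names(out) <- cols
  attr(out, "raw") <- raw
  out
}

#' Summarize a processed cohort
#'
#' Aggregates fully processed duos into a
#' \code{\linkS4class{CohortSummary}}: per-pair category-by-class count
#' rows with the half-up-rounded Mean row; gene-by-category and
#' gene-by-ontology matrices over the oncogenic and likely-oncogenic
#' variants; per-sample tumor-mutation-rate rows; and the per-pair
#' heterogeneity trend. Aggregation is pure — upstream objects are never
#' modified.
#'
#' @param duos list with one element per pair, each a list with:
#'   \code{assignment} (a \code{DuoAssignment}), \code{calls} (data.frame
#'   key / score / oclass covering the assigned variants),
#'   \code{annotations} (data.frame with key, gene, seq_ontology), and
#'   optionally \code{metrics_P}, \code{metrics_R}
#'   (\code{SampleMetrics}).
#' @return a \code{CohortSummary}.
#' @export
summarizeCohort <- function(duos) {
  stopifnot(length(duos) >= 1L)
  rows <- list()
  gene_cat <- list()
  gene_onto <- list()
  tmr_rows <- list()
  trends <- list()
  for (d in duos) {
    pid <- pairId(d$assignment)
    row <- countCategories(d$assignment, d$calls)
    rows[[pid]] <- cbind(pair = pid, row)
    a <- assignments(d$assignment)
    idx <- match(a$key, d$calls$key)
    keep <- d$calls$oclass[idx] %in% c("ONCOGENIC", "LIKELY_ONCOGENIC")
    if (any(keep)) {
      ann_idx <- match(a$key[keep], d$annotations$key)
      gene <- d$annotations$gene[ann_idx]
      onto <- d$annotations$seq_ontology[ann_idx]
      gene_cat[[pid]] <- data.frame(gene = gene,
                                    category = a$category[keep])
      gene_onto[[pid]] <- data.frame(gene = gene, ontology = onto)
    }
    if (!is.null(d$metrics_P)) {
      tmr_rows[[paste0(pid, "_P")]] <-
        tmrRow(d$metrics_P@sampleId, d$metrics_P@total_mutations,
               d$metrics_P@capture_mb)
      tmr_rows[[paste0(pid, "_R")]] <-
        tmrRow(d$metrics_R@sampleId, d$metrics_R@total_mutations,
               d$metrics_R@capture_mb)
      trend <- if (is.na(d$metrics_P@math_score) ||
                   is.na(d$metrics_R@math_score)) NA_character_
               else heterogeneityTrend(d$metrics_P, d$metrics_R)
      trends[[pid]] <- data.frame(pair = pid, trend = trend)
    }
  }
  pair_counts <- do.call(rbind, rows)
  rownames(pair_counts) <- NULL
  toMatrix <- function(lst, col) {
    if (length(lst) == 0L)
      return(matrix(integer(0), 0L, 0L))
    df <- do.call(rbind, lst)
    tab <- table(df$gene, df[[col]])
    matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  }
  new("CohortSummary",
      pairCounts = pair_counts,
      meanRow = summarizeCounts(pair_counts),
      geneByCategory = toMatrix(gene_cat, "category"),
      geneByOntology = toMatrix(gene_onto, "ontology"),
      tmrRows = if (length(tmr_rows)) do.call(rbind, tmr_rows)
                else data.frame(),
      trends = if (length(trends)) do.call(rbind, trends)
               else data.frame())
}

setMethod("show", "CohortSummary", function(object) {
  cat("CohortSummary over", nrow(object@pairCounts), "pair(s)\n")
  cat("Mean row:\n")
  print(object@meanRow, row.names = FALSE)
})

#' Table of recurrent catalogued variants
#'
#' Oncogenic / likely-oncogenic variants with a catalogue sample count of
#' at least \code{min_catalogue_count} (default 15), sorted by count
#' descending — the variants a cohort shares with other tumor types.
#'
#' @param calls data.frame of classified variants with at least
#'   \code{oclass} and \code{cosmic_count} columns; other columns pass
#'   through.
#' @param min_catalogue_count minimum catalogue sample count.
#' @return the filtered, sorted data.frame.
#' @export
recurrentVariantTable <- function(calls, min_catalogue_count = 15L) {
  if (nrow(calls) == 0L) return(calls)
  keep <- calls$oclass %in% c("ONCOGENIC", "LIKELY_ONCOGENIC") &
    calls$cosmic_count >= min_catalogue_count
  out <- calls[keep, , drop = FALSE]
  out <- out[order(-out$cosmic_count), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a cohort summary to a directory
#'
#' Emits pair_counts.tsv (with the Mean row appended),
#' gene_by_category.tsv, gene_by_ontology.tsv, tmr.tsv and trends.tsv.
#'
#' @param summary a \code{CohortSummary}.
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
writeCohortSummary <- function(summary, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pc <- rbind(summary@pairCounts,
              cbind(pair = "Mean", summary@meanRow))
  utils::write.table(pc, file.path(out_dir, "pair_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeMat <- function(m, f) {
    if (length(m))
      utils::write.table(cbind(gene = rownames(m), as.data.frame.matrix(m)),
                         file.path(out_dir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
  }
  writeMat(summary@geneByCategory, "gene_by_category.tsv")
  writeMat(summary@geneByOntology, "gene_by_ontology.tsv")
  if (nrow(summary@tmrRows))
    utils::write.table(summary@tmrRows, file.path(out_dir, "tmr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(summary@trends))
    utils::write.table(summary@trends, file.path(out_dir, "trends.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Bundled reference-cohort tables
#'
#' Published summary tables of a 10-pair primary/recurrent glioblastoma
#' exome cohort, shipped as plain-text fixtures:
#' \code{referenceCohortCounts()} returns the per-pair
#' category-by-oncogenicity-class counts, \code{referenceCohortTmr()} the
#' per-sample tumor-mutation-rate rows (totals plus the printed per-Mb and
#' log10 values), and \code{referenceRecurrentVariants()} the recurrent
#' catalogued variants with their classifier scores and catalogue counts.
#'
#' @return a data.frame.
#' @export
referenceCohortCounts <- function() {
  utils::read.delim(system.file("extdata", "reference_cohort_counts.tsv",
                                package = "DuoTriage", mustWork = TRUE))
}

#' @rdname referenceCohortCounts
#' @export
referenceCohortTmr <- function() {
  utils::read.delim(system.file("extdata", "reference_cohort_tmr.tsv",
                                package = "DuoTriage", mustWork = TRUE),
                    colClasses = c("character", "integer", "numeric",
                                   "numeric"))
}

#' @rdname referenceCohortCounts
#' @export
referenceRecurrentVariants <- function() {
  utils::read.delim(system.file("extdata",
                                "reference_recurrent_variants.tsv",
                                package = "DuoTriage", mustWork = TRUE))
}
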