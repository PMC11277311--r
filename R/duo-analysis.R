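## Shared/private categorization of a matched primary/recurrent pair, with
## the cross-sample rescue search: a variant passing the cascade in one
## member is looked up allele-exactly in the partner's calls, and counted
## as shared when the partner shows sufficient read support even though it
## failed the filters there (typical for FFPE-degraded material).

#' Construct a rescue configuration
#'
#' @param min_partner_alt_reads minimum alternate reads in the partner
#'   (default 5).
#' @param min_partner_vaf minimum partner VAF (default 0.05).
#' @param search_raw search the partner's pre-filter calls (default TRUE)
#'   rather than its cascade survivors.
#' @return a \code{RescueConfig}.
#' @export
RescueConfig <- function(min_partner_alt_reads = 5L, min_partner_vaf = 0.05,
                         search_raw = TRUE) {
  new("RescueConfig",
      min_partner_alt_reads = as.integer(min_partner_alt_reads),
      min_partner_vaf = min_partner_vaf, search_raw = search_raw)
}

#' Look up a variant in the partner sample
#'
#' Allele-exact search of \code{variant_key} in the partner's records; the
#' variant is rescued when a matching record has at least
#' \code{min_partner_alt_reads} alternate reads and a VAF of at least
#' \code{min_partner_vaf}.
#'
#' @param variant_key key as built by \code{\link{makeVariantKey}}.
#' @param partner_records the partner sample's \code{VariantSet}
#'   (pre-cascade when \code{search_raw}).
#' @param rescue_config a \code{RescueConfig}.
#' @return list with \code{rescued} (logical) and, when rescued,
#'   \code{partner_alt_depth} and \code{partner_vaf} evidence.
#' @export
rescueLookup <- function(variant_key, partner_records,
                         rescue_config = RescueConfig()) {
  v <- variantTable(partner_records)
  hit <- which(makeVariantKey(v) == variant_key &
               v$alt_depth >= rescue_config@min_partner_alt_reads &
               v$vaf >= rescue_config@min_partner_vaf)
  if (length(hit) == 0L)
    return(list(rescued = FALSE, partner_alt_depth = NA_integer_,
                partner_vaf = NA_real_))
  list(rescued = TRUE, partner_alt_depth = v$alt_depth[hit[1L]],
       partner_vaf = v$vaf[hit[1L]])
}

#' Categorize a duo's variants into primary-only / recurrent-only / shared
#'
#' The union of both samples' cascade-passing variants is partitioned:
#' a variant passing in both samples is SHARED; one passing only in the
#' primary is SHARED if the rescue lookup finds it in the recurrent
#' sample's calls, else P_ONLY, and symmetrically for the recurrent sample.
#' Shared variants are counted once per pair.
#'
#' @param passing_P,passing_R cascade-passing \code{VariantSet}s of the
#'   primary and recurrent samples.
#' @param raw_P,raw_R the same samples' pre-cascade annotated
#'   \code{VariantSet}s, searched during rescue when
#'   \code{rescue_config@search_raw} (otherwise the passing sets are
#'   searched).
#' @param rescue_config a \code{RescueConfig}.
#' @param pair_id pair identifier; defaults to
#'   "<primary sample>|<recurrent sample>".
#' @return a \code{\linkS4class{DuoAssignment}}.
#' @export
categorizeDuo <- function(passing_P, passing_R, raw_P, raw_R,
                          rescue_config = RescueConfig(),
                          pair_id = paste(sampleId(passing_P),
                                          sampleId(passing_R), sep = "|")) {
  if (sampleId(passing_P) != sampleId(raw_P) ||
      sampleId(passing_R) != sampleId(raw_R))
    stop("passing and raw sets belong to different samples; pair mismatch")
  keys_P <- variantKeys(passing_P)
  keys_R <- variantKeys(passing_R)
  search_P <- if (rescue_config@search_raw) raw_P else passing_P
  search_R <- if (rescue_config@search_raw) raw_R else passing_R

  all_keys <- union(keys_P, keys_R)
  category <- character(length(all_keys))
  rescues <- list()
  for (i in seq_along(all_keys)) {
    k <- all_keys[i]
    in_P <- k %in% keys_P
    in_R <- k %in% keys_R
    if (in_P && in_R) {
      category[i] <- "SHARED"
    } else if (in_P) {
      hit <- rescueLookup(k, search_R, rescue_config)
      if (hit$rescued) {
        category[i] <- "SHARED"
        rescues[[length(rescues) + 1L]] <-
          data.frame(key = k, rescued_in = sampleId(raw_R),
                     partner_alt_depth = hit$partner_alt_depth,
                     partner_vaf = hit$partner_vaf)
      } else category[i] <- "P_ONLY"
    } else {
      hit <- rescueLookup(k, search_P, rescue_config)
      if (hit$rescued) {
        category[i] <- "SHARED"
        rescues[[length(rescues) + 1L]] <-
          data.frame(key = k, rescued_in = sampleId(raw_P),
                     partner_alt_depth = hit$partner_alt_depth,
                     partner_vaf = hit$partner_vaf)
      } else category[i] <- "R_ONLY"
    }
  }
  rescue_df <- if (length(rescues)) do.call(rbind, rescues)
               else data.frame(key = character(0), rescued_in = character(0),
                               partner_alt_depth = integer(0),
                               partner_vaf = numeric(0))
  new("DuoAssignment", pairId = pair_id,
      assignments = data.frame(key = all_keys, category = category,
                               stringsAsFactors = FALSE),
      rescueEvents = rescue_df)
}

#' Count a duo's variants per category and oncogenicity class
#'
#' Tallies SUM / Oncogenic / Likely-oncogenic / VUS counts for each of the
#' primary-only, recurrent-only and shared categories; SUM = O + LO + VUS
#' in every category by construction.
#'
#' @param assignment a \code{DuoAssignment}.
#' @param classified_calls data.frame with columns \code{key} and
#'   \code{oclass} (ONCOGENIC / LIKELY_ONCOGENIC / VUS) covering every
#'   assigned variant; an unclassified variant is an error.
#' @return one-row data.frame with columns P_SUM, P_O, P_LO, P_VUS, R_SUM,
#'   R_O, R_LO, R_VUS, S_SUM, S_O, S_LO, S_VUS.
#' @export
countCategories <- function(assignment, classified_calls) {
  a <- assignments(assignment)
  idx <- match(a$key, classified_calls$key)
  if (anyNA(idx))
    stop("unclassified variant(s): ",
         paste(utils::head(a$key[is.na(idx)], 5L), collapse = ", "))
  oclass <- factor(classified_calls$oclass[idx],
                   levels = c("ONCOGENIC", "LIKELY_ONCOGENIC", "VUS"))
  if (anyNA(oclass)) stop("invalid oncogenicity class among calls")
  cat3 <- factor(a$category, levels = c("P_ONLY", "R_ONLY", "SHARED"))
  tab <- table(cat3, oclass)
  row <- function(cat) {
    o <- tab[cat, "ONCOGENIC"]; lo <- tab[cat, "LIKELY_ONCOGENIC"]
    vus <- tab[cat, "VUS"]
    c(SUM = o + lo + vus, O = o, LO = lo, VUS = vus)
  }
  p <- row("P_ONLY"); r <- row("R_ONLY"); s <- row("SHARED")
  out <- data.frame(P_SUM = p["SUM"], P_O = p["O"], P_LO = p["LO"],
                    P_VUS = p["VUS"], R_SUM = r["SUM"], R_O = r["O"],
                    R_LO = r["LO"], R_VUS = r["VUS"], S_SUM = s["SUM"],
                    S_O = s["O"], S_LO = s["LO"], S_VUS = s["VUS"])
  rownames(out) <- NULL
  out
}

#' Write a duo assignment table
#'
#' One TSV row per variant with its category and, for rescued variants,
#' the partner-sample evidence.
#'
#' @param assignment a \code{DuoAssignment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDuoAssignment <- function(assignment, path) {
  a <- assignments(assignment)
  r <- rescueEvents(assignment)
  idx <- match(a$key, r$key)
  out <- cbind(pair_id = pairId(assignment), a,
               rescued_in = r$rescued_in[idx],
               partner_alt_depth = r$partner_alt_depth[idx],
               partner_vaf = r$partner_vaf[idx])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
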