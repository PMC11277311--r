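## Synthetic paired primary/recurrent cohort generator with planted ground
## truth. The generator emulates the statistical structure the triage
## assumes: trunk (shared) variants drawn from clone-conditioned VAF
## centers in both samples, sample-private variants, low-VAF caller-flagged
## C>T artifacts (FFPE-style deamination), and germline common
## polymorphisms with high population allele frequencies. Expected cascade
## fates and duo categories are recomputed from the truth table by
## expectedCounts() via direct enumeration — deliberately an independent
## code path from the S4 pipeline, so end-to-end agreement is a real
## cross-check.

#' Planted ground truth of a simulated duo
#'
#' @slot occurrences data.frame, one row per (variant, sample) occurrence:
#'   sample ("P"/"R"), key, coordinates, origin label (trunk / private_P /
#'   private_R / artifact / polymorphism), clone index, driver flag,
#'   planted-rescue flag, realized depth / alternate depth / VAF and caller
#'   flags.
#' @slot annotations annotation table (the module's TSV dialect, one row
#'   per variant key).
#' @slot panel panel gene symbols.
#' @slot pairId pair identifier.
#' @export
setClass("SyntheticTruth",
         representation(occurrences = "data.frame",
                        annotations = "data.frame",
                        panel = "character",
                        pairId = "character"))

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth for pair '", object@pairId, "': ",
      nrow(object@occurrences), " occurrence(s), ",
      length(unique(object@occurrences$key)), " distinct variant(s)\n",
      sep = "")
})

#' Construct a simulation configuration
#'
#' See \code{\linkS4class{SimConfig}} for the parameter semantics and
#' defaults.
#'
#' @param seed RNG seed; the whole simulation is reproducible given it.
#' @param capture_mb capture size in megabases.
#' @param n_trunk,n_private_P,n_private_R true somatic variant counts.
#' @param clone_vaf_centers_P,clone_vaf_centers_R clonal VAF centers.
#' @param clone_sd VAF standard deviation around a clone center.
#' @param n_artifacts_P,n_artifacts_R caller-flagged low-VAF artifacts.
#' @param artifact_vaf_range artifact VAF range (uniform draw).
#' @param n_polymorphisms germline common polymorphisms (present in both
#'   samples).
#' @param depth_mean mean sequencing depth (Poisson).
#' @param panel_fraction fraction of true variants planted as drivers in
#'   panel genes.
#' @param n_rescue_trunk trunk variants degraded below the level-1 VAF
#'   threshold in the recurrent sample but kept above the rescue floor.
#' @param driver_catalogue data.frame of planted-driver gene annotations;
#'   default \code{\link{defaultDriverCatalogue}()}.
#' @return a \code{SimConfig}.
#' @export
SimConfig <- function(seed = 1L, capture_mb = 42, n_trunk = 8L,
                      n_private_P = 20L, n_private_R = 30L,
                      clone_vaf_centers_P = c(0.25, 0.45),
                      clone_vaf_centers_R = c(0.22, 0.40),
                      clone_sd = 0.03, n_artifacts_P = 15L,
                      n_artifacts_R = 15L,
                      artifact_vaf_range = c(0.01, 0.10),
                      n_polymorphisms = 10L, depth_mean = 180L,
                      panel_fraction = 0.6, n_rescue_trunk = 1L,
                      driver_catalogue = defaultDriverCatalogue()) {
  new("SimConfig", seed = as.integer(seed), capture_mb = capture_mb,
      n_trunk = as.integer(n_trunk), n_private_P = as.integer(n_private_P),
      n_private_R = as.integer(n_private_R),
      clone_vaf_centers_P = clone_vaf_centers_P,
      clone_vaf_centers_R = clone_vaf_centers_R, clone_sd = clone_sd,
      n_artifacts_P = as.integer(n_artifacts_P),
      n_artifacts_R = as.integer(n_artifacts_R),
      artifact_vaf_range = artifact_vaf_range,
      n_polymorphisms = as.integer(n_polymorphisms),
      depth_mean = as.integer(depth_mean),
      panel_fraction = panel_fraction,
      n_rescue_trunk = as.integer(n_rescue_trunk),
      driver_catalogue = driver_catalogue)
}

#' The shipped driver catalogue
#'
#' Small catalogue of cancer genes (symbol, cancer-gene role, typical
#' sequence-ontology spectrum) from which the simulator draws planted
#' drivers, so synthetic reports resemble real glioma gene-level summaries
#' without external data.
#'
#' @return data.frame with columns gene, gene_role, ontologies
#'   (comma-joined).
#' @export
defaultDriverCatalogue <- function() {
  path <- system.file("extdata", "driver_catalogue.tsv",
                      package = "DuoTriage", mustWork = TRUE)
  utils::read.delim(path, colClasses = "character")
}

.BASES <- c("A", "C", "G", "T")

## draw an ontology/effect pair consistent with a catalogue gene
.draw_consequence <- function(ontologies) {
  onto <- sample(strsplit(ontologies, ",", fixed = TRUE)[[1L]], 1L)
  effect <- switch(onto,
                   missense = "missense",
                   frameshift = "LoF",
                   stop_gained = "LoF",
                   splice_variant = "LoF",
                   "other")
  list(onto = onto, effect = effect)
}

#' Simulate an annotated primary/recurrent duo with known truth
#'
#' Generates the full input bundle of a duo analysis — two single-sample
#' VCFs, the annotation TSV, a panel file — together with the
#' \code{\linkS4class{SyntheticTruth}} bookkeeping. Trunk variants appear
#' in both samples with clone-conditioned VAFs; private variants in one;
#' artifacts carry excluded caller flags at low VAF; polymorphisms carry
#' population allele frequencies >= 2\% and common-polymorphism membership.
#' Depths are Poisson about \code{depth_mean}; the alternate depth is
#' \code{round(vaf * depth)} and the realized VAF is recomputed from it,
#' so the written files are internally consistent. Byte-identical outputs
#' for a fixed seed.
#'
#' @param config a \code{SimConfig}.
#' @param out_dir directory for the generated files (created if needed).
#' @param pair_id pair identifier (default "duo1").
#' @return list with paths \code{vcf_P}, \code{vcf_R}, \code{annotations},
#'   \code{panel}, \code{truth_tsv} and the \code{truth} object.
#' @export
simulateDuo <- function(config = SimConfig(), out_dir = tempfile("duo"),
                        pair_id = "duo1") {
  validObject(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config@seed)
  catalogue <- config@driver_catalogue
  if (nrow(catalogue) == 0L) catalogue <- defaultDriverCatalogue()

  n_true <- config@n_trunk + config@n_private_P + config@n_private_R
  n_total <- n_true + config@n_artifacts_P + config@n_artifacts_R +
    config@n_polymorphisms
  if (n_total == 0L) stop("simulation with zero variants requested")

  ## unique loci: unique positions guarantee unique keys
  chrom <- as.character(sample(1:22, n_total, replace = TRUE))
  pos <- sample(10000:50000000, n_total)
  ref <- sample(.BASES, n_total, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1L),
                character(1L))

  origin <- rep(c("trunk", "private_P", "private_R", "artifact_P",
                  "artifact_R", "polymorphism"),
                c(config@n_trunk, config@n_private_P, config@n_private_R,
                  config@n_artifacts_P, config@n_artifacts_R,
                  config@n_polymorphisms))
  is_artifact <- origin %in% c("artifact_P", "artifact_R")
  ref[is_artifact] <- "C"
  alt[is_artifact] <- "T"

  vdf <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    origin = origin, stringsAsFactors = FALSE)
  vdf$key <- makeVariantKey(vdf)
  vdf$is_driver <- FALSE
  vdf$rescue_planted <- FALSE
  vdf$clone <- NA_integer_

  true_idx <- which(origin %in% c("trunk", "private_P", "private_R"))
  if (length(true_idx)) {
    vdf$is_driver[true_idx] <-
      stats::runif(length(true_idx)) < config@panel_fraction
    n_clones <- max(length(config@clone_vaf_centers_P),
                    length(config@clone_vaf_centers_R))
    vdf$clone[true_idx] <- sample.int(max(n_clones, 1L),
                                      length(true_idx), replace = TRUE)
  }
  rescue_idx <- utils::head(which(origin == "trunk"),
                            config@n_rescue_trunk)
  vdf$rescue_planted[rescue_idx] <- TRUE
  vdf$is_driver[rescue_idx] <- TRUE  # rescue path must survive the cascade

  ## --- annotations, one row per variant key -------------------------------
  ann <- defaultAnnotationBundle()[rep(1L, n_total), , drop = FALSE]
  rownames(ann) <- NULL
  for (i in seq_len(n_total)) {
    o <- vdf$origin[i]
    if (o == "polymorphism") {
      ann$af_1kg[i] <- stats::runif(1L, 0.05, 0.40)
      ann$af_gnomad_exome[i] <- stats::runif(1L, 0.05, 0.40)
      ann$maf_esp[i] <- stats::runif(1L, 0.05, 0.40)
      ann$dbsnp_common[i] <- TRUE
      ann$seq_ontology[i] <- "missense"
      ann$effect[i] <- "missense"
      ann$gene[i] <- paste0("POLYGENE", i)
    } else if (o %in% c("artifact_P", "artifact_R")) {
      ann$seq_ontology[i] <- "other"   # default bundle: fails relevance too
      ann$gene[i] <- paste0("ARTGENE", i)
    } else if (vdf$is_driver[i]) {
      row <- catalogue[sample.int(nrow(catalogue), 1L), ]
      cons <- .draw_consequence(row$ontologies)
      ann$gene[i] <- row$gene
      ann$gene_role[i] <- row$gene_role
      ann$seq_ontology[i] <- cons$onto
      ann$effect[i] <- cons$effect
      ann$cosmic_count[i] <- sample(c(1:8, 15:40, 60:120), 1L)
      ann$cosmic_ids[i] <- paste0("COSMSYN", i)
      nvotes <- sample.int(6L, 1L)
      for (p in .PREDICTORS[seq_len(nvotes)]) ann[[p]][i] <- "damaging"
      for (p in setdiff(.PREDICTORS, .PREDICTORS[seq_len(nvotes)]))
        ann[[p]][i] <- "tolerated"
      ann$clinical_class[i] <- "other"
      ann$hgvs_c[i] <- paste0("c.", vdf$pos[i] %% 5000 + 1, vdf$ref[i],
                              ">", vdf$alt[i])
      ann$hgvs_p[i] <- "p.?"
    } else {
      ## non-driver true variant: plant one relevance/panel fail mode
      mode <- sample(c("ontology", "no_catalogue", "off_panel", "benign"),
                     1L)
      ann$gene[i] <- paste0("FILLER", i)
      if (mode == "ontology") {
        ann$seq_ontology[i] <- sample(c("synonymous", "intron",
                                        "intragenic", "initiator_codon"),
                                      1L)
        ann$effect[i] <- "other"
        ann$cosmic_ids[i] <- paste0("COSMSYN", i)
        ann$cosmic_count[i] <- sample.int(5L, 1L)
        ann$sift[i] <- "damaging"
      } else if (mode == "no_catalogue") {
        ann$seq_ontology[i] <- "missense"
        ann$effect[i] <- "missense"
        ann$sift[i] <- "damaging"
      } else if (mode == "off_panel") {
        ann$seq_ontology[i] <- "missense"
        ann$effect[i] <- "missense"
        ann$cosmic_ids[i] <- paste0("COSMSYN", i)
        ann$cosmic_count[i] <- sample.int(5L, 1L)
        ann$sift[i] <- "damaging"
      } else {
        ann$seq_ontology[i] <- "missense"
        ann$effect[i] <- "missense"
        ann$cosmic_ids[i] <- paste0("COSMSYN", i)
        ann$cosmic_count[i] <- sample.int(5L, 1L)
        ann$sift[i] <- "damaging"
        ann$clinical_class[i] <- sample(c("benign", "likely_benign",
                                          "vus_weak_benign"), 1L)
      }
    }
  }
  annotations <- cbind(vdf[c("chrom", "pos", "ref", "alt")], ann)

  ## --- per-sample occurrences ---------------------------------------------
  centers_for <- function(sample, clone) {
    ctr <- if (sample == "P") config@clone_vaf_centers_P
           else config@clone_vaf_centers_R
    ctr[(clone - 1L) %% length(ctr) + 1L]
  }
  drawVaf <- function(center)
    min(max(stats::rnorm(1L, center, config@clone_sd), 0.02), 0.95)

  occ <- list()
  addOccurrence <- function(i, sample, vaf, flags = "") {
    dp <- stats::rpois(1L, config@depth_mean)
    dp <- max(dp, 1L)
    ad <- min(max(round(vaf * dp), 0L), dp)
    occ[[length(occ) + 1L]] <<-
      data.frame(sample = sample, key = vdf$key[i], chrom = vdf$chrom[i],
                 pos = vdf$pos[i], ref = vdf$ref[i], alt = vdf$alt[i],
                 origin = if (grepl("^artifact_", vdf$origin[i]))
                   "artifact" else vdf$origin[i],
                 clone = vdf$clone[i], is_driver = vdf$is_driver[i],
                 rescue_planted = vdf$rescue_planted[i],
                 total_depth = dp, alt_depth = ad,
                 vaf = if (dp > 0L) ad / dp else 0,
                 caller_flags = flags, stringsAsFactors = FALSE)
  }

  for (i in seq_len(n_total)) {
    o <- vdf$origin[i]
    if (o == "trunk") {
      if (vdf$rescue_planted[i]) {
        addOccurrence(i, "P", min(max(stats::rnorm(
          1L, max(config@clone_vaf_centers_P, 0.30), config@clone_sd),
          0.20), 0.95))
        addOccurrence(i, "R", stats::runif(1L, 0.06, 0.12))
      } else {
        addOccurrence(i, "P", drawVaf(centers_for("P", vdf$clone[i])))
        addOccurrence(i, "R", drawVaf(centers_for("R", vdf$clone[i])))
      }
    } else if (o == "private_P") {
      addOccurrence(i, "P", drawVaf(centers_for("P", vdf$clone[i])))
    } else if (o == "private_R") {
      addOccurrence(i, "R", drawVaf(centers_for("R", vdf$clone[i])))
    } else if (o == "artifact_P") {
      addOccurrence(i, "P", stats::runif(1L, config@artifact_vaf_range[1L],
                                         config@artifact_vaf_range[2L]),
                    flags = sample(c("strand_bias", "fragment"), 1L))
    } else if (o == "artifact_R") {
      addOccurrence(i, "R", stats::runif(1L, config@artifact_vaf_range[1L],
                                         config@artifact_vaf_range[2L]),
                    flags = sample(c("strand_bias", "fragment"), 1L))
    } else {
      vaf_g <- stats::runif(1L, 0.35, 0.65)
      addOccurrence(i, "P", vaf_g)
      addOccurrence(i, "R", vaf_g)
    }
  }
  occurrences <- do.call(rbind, occ)

  ## --- write the artifact bundle ------------------------------------------
  panel <- sort(unique(catalogue$gene))
  truth <- new("SyntheticTruth", occurrences = occurrences,
               annotations = annotations, panel = toupper(panel),
               pairId = pair_id)

  vcf_P <- file.path(out_dir, paste0(pair_id, "_P.vcf"))
  vcf_R <- file.path(out_dir, paste0(pair_id, "_R.vcf"))
  .writeSimpleVcf(occurrences[occurrences$sample == "P", ],
                  paste0(pair_id, "_P"), vcf_P)
  .writeSimpleVcf(occurrences[occurrences$sample == "R", ],
                  paste0(pair_id, "_R"), vcf_R)
  ann_path <- file.path(out_dir, paste0(pair_id, "_annotations.tsv"))
  writeAnnotations(annotations, ann_path)
  panel_path <- file.path(out_dir, paste0(pair_id, "_panel.txt"))
  writeLines(c("# simulated gene panel", panel), panel_path)
  truth_path <- file.path(out_dir, paste0(pair_id, "_truth.tsv"))
  utils::write.table(occurrences, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")

  list(vcf_P = vcf_P, vcf_R = vcf_R, annotations = ann_path,
       panel = panel_path, truth_tsv = truth_path, truth = truth)
}

## minimal single-sample VCF 4.2 writer for the simulator's dialect
.writeSimpleVcf <- function(occ, sample_name, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=DuoTriageSimulator",
    "##FILTER=<ID=strand_bias,Description=\"Strand bias hard filter\">",
    "##FILTER=<ID=fragment,Description=\"Fragment length hard filter\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  occ <- occ[order(as.integer(occ$chrom), occ$pos), , drop = FALSE]
  filt <- ifelse(nzchar(occ$caller_flags),
                 gsub(",", ";", occ$caller_flags, fixed = TRUE), "PASS")
  rows <- paste(occ$chrom, occ$pos, ".", occ$ref, occ$alt, ".", filt, ".",
                "GT:DP:AD",
                paste0("0/1:", occ$total_depth, ":",
                       occ$total_depth - occ$alt_depth, ",", occ$alt_depth),
                sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Predict pipeline results by direct enumeration over the truth
#'
#' Recomputes, from the truth bookkeeping alone and with straightforward
#' vectorized logic (no calls into the cascade / duo / scoring code
#' paths), everything the pipeline must reproduce on the simulated duo:
#' per-level audit counts for both samples, the shared/private duo
#' categorization with rescue, and the category-by-oncogenicity-class
#' count row.
#'
#' @param truth a \code{SyntheticTruth}.
#' @param filter_config a \code{FilterConfig}.
#' @param rescue_config a \code{RescueConfig}.
#' @return list with \code{audit_P}, \code{audit_R} (data.frames level /
#'   entering / passing), \code{categories} (data.frame key / category),
#'   and \code{counts} (one-row category-by-class data.frame as
#'   \code{\link{countCategories}}).
#' @export
expectedCounts <- function(truth, filter_config = FilterConfig(),
                           rescue_config = RescueConfig()) {
  occ <- truth@occurrences
  ann <- truth@annotations
  ann$key <- makeVariantKey(ann)
  a <- ann[match(occ$key, ann$key), ]
  cfg <- filter_config

  flagged <- vapply(strsplit(occ$caller_flags, ",", fixed = TRUE),
                    function(f)
                      length(intersect(f[nzchar(f)],
                                       cfg@excluded_caller_flags)) > 0L,
                    logical(1L))
  pass1 <- !flagged &
    occ$total_depth >= cfg@min_depth &
    occ$vaf >= cfg@min_vaf &
    occ$alt_depth >= cfg@min_alt_reads &
    (is.na(a$af_1kg) | a$af_1kg < cfg@max_af_1kg) &
    (is.na(a$af_gnomad_exome) | a$af_gnomad_exome < cfg@max_af_gnomad) &
    (is.na(a$maf_esp) | a$maf_esp < cfg@max_maf_esp) &
    !(cfg@exclude_dbsnp_common & a$dbsnp_common)

  tallyVotes <- function(df) {
    if (nrow(df) == 0L) return(integer(0))
    m <- vapply(.PREDICTORS, function(p)
      !is.na(df[[p]]) & df[[p]] == "damaging", logical(nrow(df)))
    if (nrow(df) == 1L) m <- matrix(m, nrow = 1L)
    as.integer(rowSums(m))
  }
  votes <- tallyVotes(a)
  pass2 <- pass1 &
    !(a$seq_ontology %in% cfg@excluded_ontologies) &
    votes >= cfg@min_damaging_votes &
    !(!is.na(a$clinical_class) &
        a$clinical_class %in% cfg@excluded_clinical_classes) &
    a$effect %in% cfg@retained_effects &
    (!cfg@require_cosmic | nzchar(a$cosmic_ids))

  pass3 <- pass2 &
    toupper(trimws(a$gene)) %in% truth@panel &
    a$gene_role %in% cfg@retained_gene_roles

  auditFor <- function(s) {
    sel <- occ$sample == s
    data.frame(level = 1:3,
               entering = c(sum(sel), sum(sel & pass1), sum(sel & pass2)),
               passing = c(sum(sel & pass1), sum(sel & pass2),
                           sum(sel & pass3)))
  }

  ## duo categorization with rescue, enumerated per key
  keys_P <- occ$key[occ$sample == "P" & pass3]
  keys_R <- occ$key[occ$sample == "R" & pass3]
  rescuable <- function(k, s) {
    sel <- occ$sample == s & occ$key == k &
      occ$alt_depth >= rescue_config@min_partner_alt_reads &
      occ$vaf >= rescue_config@min_partner_vaf
    if (!rescue_config@search_raw) {
      keep <- if (s == "P") keys_P else keys_R
      sel <- sel & occ$key %in% keep
    }
    any(sel)
  }
  all_keys <- union(keys_P, keys_R)
  category <- vapply(all_keys, function(k) {
    in_P <- k %in% keys_P
    in_R <- k %in% keys_R
    if (in_P && in_R) "SHARED"
    else if (in_P) { if (rescuable(k, "R")) "SHARED" else "P_ONLY" }
    else { if (rescuable(k, "P")) "SHARED" else "R_ONLY" }
  }, character(1L))

  ## oncogenicity score, re-derived arithmetically from annotations
  ak <- ann[match(all_keys, ann$key), ]
  avotes <- tallyVotes(ak)
  score <- ifelse(ak$cosmic_count >= 50L, 4L,
                  ifelse(ak$cosmic_count >= 10L, 2L,
                         ifelse(ak$cosmic_count >= 1L, 1L, 0L))) +
    ifelse(ak$effect == "LoF" & ak$gene_role == "tumor_suppressor", 4L, 0L) +
    ifelse(ak$effect == "missense" & avotes >= 3L, 2L, 0L) +
    ifelse(ak$seq_ontology == "splice_variant", 2L, 0L) +
    ifelse(ak$gene_role == "oncogene" & ak$cosmic_count >= 10L, 2L, 0L) +
    ifelse(!is.na(ak$af_1kg) | !is.na(ak$af_gnomad_exome) |
             !is.na(ak$maf_esp), -4L, 0L)
  oclass <- ifelse(score >= 5L, "ONCOGENIC",
                   ifelse(score >= 3L, "LIKELY_ONCOGENIC", "VUS"))

  tab <- table(factor(category, levels = c("P_ONLY", "R_ONLY", "SHARED")),
               factor(oclass, levels = c("ONCOGENIC", "LIKELY_ONCOGENIC",
                                         "VUS")))
  counts <- data.frame(
    P_SUM = sum(tab["P_ONLY", ]), P_O = tab["P_ONLY", 1L],
    P_LO = tab["P_ONLY", 2L], P_VUS = tab["P_ONLY", 3L],
    R_SUM = sum(tab["R_ONLY", ]), R_O = tab["R_ONLY", 1L],
    R_LO = tab["R_ONLY", 2L], R_VUS = tab["R_ONLY", 3L],
    S_SUM = sum(tab["SHARED", ]), S_O = tab["SHARED", 1L],
    S_LO = tab["SHARED", 2L], S_VUS = tab["SHARED", 3L])

  list(audit_P = auditFor("P"), audit_R = auditFor("R"),
       categories = data.frame(key = all_keys, category = category,
                               stringsAsFactors = FALSE, row.names = NULL),
       counts = counts)
}
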