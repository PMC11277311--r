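---
title: "Triage of paired primary/recurrent somatic variants: methods and design"
author: "DuoTriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of paired primary/recurrent somatic variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DuoTriage)
```

## The problem

Matched primary/recurrent tumor pairs from FFPE blocks are a common — and
awkward — substrate for exome sequencing. Formalin fixation inflates the
raw call set with low-VAF artifacts (classically C>T deamination), and an
exome over a tumor without a matched normal is saturated with common
germline polymorphisms. The variants worth a clinician's or biologist's
attention — drivers with oncogenic evidence, and their persistence or
turnover between onset and recurrence — must be distilled by an explicit,
reproducible filter chain. DuoTriage implements that chain together with
the longitudinal summaries usually reported alongside it: per-category
variant counts, tumor mutation rate, MATH heterogeneity and VAF clonality.

The package operates strictly downstream of variant calling: inputs are
per-sample VCFs in an upstream somatic caller's dialect (Mutect2-style
FILTER labels, FORMAT `DP`/`AD`), file-based annotation bundles, and a
gene panel. No live database queries, no realignment, no CNV calling.

## Data model

`VariantSet` holds one sample's calls as one row per (site, alternate
allele); multiallelic records are split on read. Two choices here are
deliberate:

- **VAF is always recomputed** as `alt_depth / total_depth` and never
  trusted from a caller AF field. The level-1 thresholds act jointly on
  depth, alternate count and VAF, so the three must be internally
  consistent; a drifting caller AF definition (e.g. local reassembly
  fractions) would make the boundary behavior irreproducible.
- **Joins are allele-exact** on `(chrom, pos, ref, alt)`. Annotation
  attachment is a left join (record set unchanged; unmatched records get
  an explicit default bundle whose `effect = "none"` guarantees they
  cannot survive the relevance level). Coordinates are 1-based VCF;
  indel left-alignment is assumed done upstream and is documented rather
  than enforced. Whether multiallelic sites should be split at all is a
  convention of this package — upstream tools differ — and splitting
  conserves alternate alleles by construction.

Missingness is first-class: a missing population frequency is `NA`,
distinct from 0, and all removal rules are written so that missing values
never fire them.

## The filter cascade

Levels are per-record predicate conjunctions, applied 1 → 2 → 3; level 4
(expert curation) is emitted as a ranked review table, not an algorithm.
Defaults, with units:

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 50 reads | minimum total depth (inclusive) |
| `min_vaf` | 0.15 | minimum variant allele fraction (inclusive) |
| `min_alt_reads` | 20 reads | minimum alternate-allele reads (inclusive) |
| `max_af_1kg`, `max_af_gnomad` | 0.02 | population AF removal at ≥ threshold |
| `max_maf_esp` | 0.05 | ESP minor AF removal at ≥ threshold |
| `exclude_dbsnp_common` | TRUE | drop common-polymorphism members |
| `excluded_ontologies` | initiator codon, intragenic, intron, synonymous | irrelevant consequences |
| `min_damaging_votes` | 1 of 6 | in-silico predictor support |
| `excluded_clinical_classes` | benign, likely benign, weak-benign VUS | clinically dismissed classes |
| `retained_effects` | LoF, missense, other, unknown | effect classes kept |
| `require_cosmic` | TRUE | demand ≥ 1 catalogue record |
| `retained_gene_roles` | oncogene, tumor suppressor, fusion | level-3 role restriction |
| `excluded_caller_flags` | strand_bias, fragment | upstream hard-filter labels |

Three interpretation points were genuinely open and are resolved as
follows:

- **Direction of the predictor-vote rule.** Read literally, some pipeline
  descriptions of this kind discard variants that any predictor calls
  damaging; that contradicts the enrichment goal (the retained classes
  are the oncogenic ones). DuoTriage retains a variant when at least
  `min_damaging_votes` predictors call it damaging, with the threshold
  exposed; missing verdicts count zero.
- **Boundary semantics.** Evidence thresholds are inclusive retentions
  (DP = 50, VAF = 0.15, alt = 20 pass); population frequencies are
  removals at ≥ threshold, and missing frequencies are retained. Both
  follow the stated settings of the emulated pipeline and are pinned by
  boundary tests.
- **First-fail ordering.** Within a level the passing set is
  order-independent (a pure conjunction), but audit reasons need a
  convention: the fixed rule order is caller flag, depth, VAF, alternate
  reads, 1kG AF, gnomAD AF, ESP MAF, dbSNP; ontology, prediction,
  clinical class, effect, catalogue; panel, gene role. Whether the
  polymorphism rules run before or after the frequency rules does not
  change what passes, only which reason an excluded polymorphism gets —
  fixing the order makes audits deterministic.

One emulated filter card ("technically hard to detect" flags of the
original proprietary software) has no public definition; the configurable
`excluded_caller_flags` list is the hook that stands in its place.

`FilterAudit` enforces conservation invariants by validity:
`passing(k) = entering(k+1)`, and per level the removed-variant tally
equals `entering − passing`.

## Duo categorization and rescue

After filtering each sample independently, the union of survivors is
partitioned into P-only / R-only / shared. The rescue step reflects how
paired designs are analyzed in practice: a trunk variant can fail hard
thresholds in one member of the pair purely through FFPE degradation, so
a variant passing in one sample is searched allele-exactly in the
partner's **pre-filter** calls (`search_raw = TRUE`; the alternative —
searching only the partner's survivors — is a switch). The rescue
evidence thresholds (≥ 5 alternate reads, VAF ≥ 5%) are this package's
own defaults: the proprietary pairwise filter card they replace is
undocumented, and the chosen floor demands multi-read support while
tolerating several-fold VAF degradation. They are fully configurable, and
shared counts are monotone in them (loosening never loses a shared call —
a property test).

Shared variants are counted once per pair; counting by oncogenicity class
(`countCategories`) requires every assigned variant to carry a class and
errors otherwise, rather than silently dropping.

## Oncogenicity scoring

The class thresholds are the published ones: score ≥ 5 Oncogenic, 3–4
Likely oncogenic, ≤ 2 (including negatives) VUS — consistent with every
reference score/class pair bundled with the package. The points rubric
itself is this package's replaceable stand-in for a proprietary
classifier, written in the spirit of published points-based oncogenicity
SOPs: catalogue-recurrence tiers (+4 at ≥ 50 samples, +2 at ≥ 10, +1 at
≥ 1; tiers exclusive), LoF in a tumor suppressor (+4), missense with ≥ 3
damaging votes (+2), splice disruption (+2), recurrent oncogene (+2),
any recorded population frequency (−4). Additivity is a modeling choice,
flagged here; if an external score column is available,
`scoreFromColumn()` bypasses the rubric and applies only the thresholds.

## Longitudinal metrics

All three metrics are computed on the **level-1-passing** set: technical
quality enforced, biological-relevance filtering withheld so the VAF
distribution is not biased toward drivers.

- **TMR** = level-1 mutations / capture megabases (default 42 Mb, the
  emulated capture). This is a longitudinal comparison measure; it is not
  TMB, which is computed from classified variants under assay-specific
  rules. The rate is exact; presentation rounds half-up to 2 decimals
  with raw values carried alongside. `log10` of a zero rate is undefined
  and reported `NA`.
- **MATH** = 100 · MAD/median of the VAFs; the MAD uses the
  normal-consistency constant 1.4826 (the convention of the original
  score implementation; configurable to 1). A zero median yields `NA`
  with a warning. The score is scale-invariant under VAF rescaling.
- **VAF mixture.** A 1-D Gaussian mixture is fitted by EM for
  k = 1..`max_components` (default 5) in equal-variance and
  free-variance families, selected by BIC (`−2·loglik + p·log n`; ties
  resolved toward the earlier candidate, i.e. smaller k and the
  equal-variance family). Initialization is deterministic — component
  means at the k mid-quantiles, equal weights, pooled variance — so fits
  are order-invariant and reproducible without consuming the seed; the
  seed is recorded and used only if jittered restarts are requested.
  Numerical guards: variance floor 1e-6 (components cannot collapse onto
  points), density floor 1e-300 before logs, convergence at
  log-likelihood change < 1e-8, 500-iteration cap, and a per-fit check
  that the log-likelihood never decreases. Fewer than 2k observations
  shrink the candidate range with a warning, down to a single component.
  The independent mclust implementation is used in the test suite as a
  cross-check oracle on simulated data, never as the implementation.

## Cohort reporting conventions

Per-pair category counts are summarized with a Mean row. The bundled
reference table rounds each O/LO/VUS class mean half-up to an integer and
presents each SUM as the sum of its rounded class means — preserving the
SUM = O + LO + VUS identity in the Mean row, at the cost of occasionally
differing by one from rounding the SUM mean directly. `summarizeCounts()`
follows that convention and attaches the raw means. One per-Mb value in
the bundled reference TMR table (609.99) is arithmetically impossible for
any integer count over 42 Mb; the tests assert the recomputed value
(609.98) and one-unit-last-digit agreement with the print.

The recurrent-variant report keeps oncogenic/likely-oncogenic variants
with catalogue count ≥ 15 (default), sorted by count descending. Gene
matrices in `CohortSummary` are plain count matrices; figures are left to
the user, and tests assert the matrices, not images.

## The synthetic cohort: what it does and does not emulate

`simulateDuo()` plants, per pair: trunk variants present in both samples
with VAFs drawn `N(center, clone_sd)` from clone-specific centers
(defaults: primary centers 0.25/0.45, recurrent 0.22/0.40, sd 0.03);
sample-private variants; low-VAF C>T artifacts carrying an excluded
caller flag (VAF uniform on 0.01–0.10); and germline polymorphisms
present in both samples with population AFs ≥ 5% and dbSNP-common
membership. Depths are Poisson with mean 180 (the coverage scale of the
emulated FFPE exomes); `alt_depth = round(vaf · depth)` and the realized
VAF is recomputed from it, so written files are internally consistent.
A configurable number of trunk variants (default 1) is degraded in the
recurrent sample to VAF 0.06–0.12 — below the level-1 threshold, above
the rescue floor — and forced to driver annotation, exercising the rescue
path end to end. Driver annotations are drawn from a small shipped
catalogue of cancer genes with role-consistent consequence spectra;
non-driver true variants are planted with one of four explicit fail
modes (excluded ontology, no catalogue record, off-panel gene, benign
class) so every cascade rule sees traffic.

`expectedCounts()` recomputes the audits, categories and class counts by
direct vectorized enumeration over the truth table — an implementation
deliberately disjoint from the S4 pipeline — and the suite requires exact
agreement across seeds. What passing these tests shows is that the
pipeline implements its own rules correctly; what it cannot show is
realism beyond the generator's assumptions. In particular the generator
draws independent per-site depths (no capture GC structure), plants
point mutations only (no indels or multiallelic sites — those are
covered by hand-built reader fixtures), uses a single artifact mechanism,
and gives every variant a complete, noise-free annotation bundle. Real
annotation sources disagree and go stale; the filters treat annotations
as given.

## Problem sizes

The shipped defaults keep the full validation cheap: simulated duos have
~100 variants per pair (53 primary-side occurrences under the defaults),
truth recovery runs 20 seeds, and mixture recovery runs 100 replicates of
n = 300 at k ≤ 5 in both families — the whole suite and the acceptance
script each complete in about two minutes on one core. All sizes are
ordinary function arguments; scaling a simulated pair to exome-like
counts (tens of thousands of level-1 calls, as in the reference TMR
table) is a matter of raising the `SimConfig` counts.

## Known limitations

- No clone-tree or phylogeny reconstruction; the shared/private partition
  plus MATH/mixture trends is as far as the longitudinal inference goes.
- The rubric is a stand-in, not a validated classifier; its scores are
  meaningful relative to its own thresholds.
- Rubric YAML serialization covers the parameterised default rules
  (points, thresholds); arbitrary predicate rules are programmatic only.
- TMR depends on the capture size constant; comparisons across assays
  with different captures are not meaningful.
- The cascade consumes caller flags as given and cannot recover calls the
  upstream caller never emitted.
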