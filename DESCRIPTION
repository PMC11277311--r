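Package: DuoTriage
Title: Somatic Variant Triage and Longitudinal Metrics for Paired Tumor Samples
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Filter-cascade triage of annotated somatic variant calls from
    matched primary/recurrent tumor pairs ("duos"), as used in longitudinal
    glioblastoma exome studies. Implements a four-level filtering pipeline
    (caller hard-filter flags, depth/VAF/alternate-read thresholds,
    population-frequency and polymorphism exclusion; sequence-ontology,
    in-silico prediction voting, clinical-class and cancer-catalogue
    relevance; gene-panel and cancer-gene-role restriction; a ranked manual
    review report) with a complete per-variant audit trail, shared/private
    duo categorization with cross-sample rescue, points-based oncogenicity
    scoring with Oncogenic/Likely-oncogenic/VUS thresholds, and per-sample
    longitudinal metrics: tumor mutation rate per megabase, MATH
    intra-tumor-heterogeneity score and VAF Gaussian-mixture clonality.
    Includes a synthetic paired-cohort generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
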