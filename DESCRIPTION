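Package: lymphCH
Title: Clonal Hematopoiesis and Late Mutations in T-Cell Lymphoma
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of paired lymph-node and bone-marrow/peripheral-blood
    variant tables from angioimmunoblastic T-cell lymphoma (AITL) and related
    peripheral T-cell lymphomas. Partitions somatic variants into early clonal
    hematopoiesis (CH)-associated and late lymphoma-specific mutations using a
    tumor-burden attribution rule, builds 96-context trinucleotide mutation
    catalogs with transcriptional strand splitting, extracts de novo
    mutational signatures by bootstrapped non-negative matrix factorization
    with cosine-similarity matching to a reference signature set, evaluates a
    multiple-hit TET2 biomarker for concomitant hematologic neoplasm risk via
    Kaplan-Meier, log-rank and Cox analyses, and computes age-standardized
    incidence-rate comparisons. Includes a synthetic-cohort generator with
    full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, survival, cluster, pracma, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'contexts.R'
    'AllClasses.R'
    'cohort-io.R'
    'partition.R'
    'catalog.R'
    'signatures.R'
    'biomarker-survival.R'
    'epi-stats.R'
    'synthetic-cohort.R'
    'pipeline.R'
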