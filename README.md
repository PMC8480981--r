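# lymphCH

Clonal hematopoiesis (CH) and late lymphoma-specific mutations in
angioimmunoblastic T-cell lymphoma (AITL) and related peripheral T-cell
lymphomas, analyzed from paired lymph-node (LN) and bone-marrow/peripheral-blood
(BM/PB) targeted-sequencing variant tables.

In AITL, somatic `TET2`/`DNMT3A` mutations shared between the lymphoma and the
patient's BM/PB indicate that the tumor arises from a mutated hematopoietic
precursor clone (CH). The package implements the analysis that follows from
this observation, for hematopathology and cancer-genomics researchers working
with paired-compartment variant calls:

- **Clonal partition.** The tumor burden (TB) of each BM/PB sample is
  estimated by a hierarchy of evidence (flow cytometry > TCRG clonality with
  its 1–5% analytic sensitivity > lymphoma-marker VAF, e.g. `RHOA` p.G17V).
  A heterozygous variant confined to neoplastic cells at tumor fraction `tb`
  has expected VAF `tb/2`; a BM/PB variant whose VAF exceeds
  `tb_high/2 × (1 + tolerance)` cannot be explained by lymphoma involvement
  alone and is attributed to CH. Variants split into `CH_shared`,
  `CH_bmpb_only`, `involvement` and `late_ln_only` (early CH-associated vs
  late lymphoma-specific mutations).
- **Mutation catalogs.** 96-context pyrimidine-collapsed trinucleotide
  catalogs (optionally strand-split to 192 bins by coding-strand
  orientation), six-class substitution spectra, Ti/Tv summaries, and
  transcriptional strand-bias fold excess `(n_fwd − n_rev)/n_rev`.
- **Signature inference.** De novo mutational signatures by bootstrapped
  non-negative matrix factorization under the generalized Kullback–Leibler
  objective (multiplicative updates), consensus by partitioning around
  medoids under cosine distance, NNLS exposure refit, cosine correlation
  similarity (CCS) matching against a 30-signature reference set, and
  per-sample dominance calls (≥50% of a sample's mutations).
- **Biomarker + survival.** The multiple-hit `TET2` biomarker (≥2 pathogenic
  tier-1/2 `TET2` variants in BM/PB, each VAF ≥15%) against CHN-free survival
  (CHN = concomitant hematologic neoplasm): Kaplan–Meier, log-rank, binary
  Cox hazard ratio (Efron ties), sensitivity/specificity/PPV/NPV, and a
  brute-force reconstruction of 2×2 confusion tables from printed
  percentages.
- **Epidemiology statistics.** Directly age-standardized incidence rates
  (`Σ cases/population × 100000 × weight`), rate ratios, pooled
  two-proportion z test, Welch t test.
- **Synthetic cohorts.** A generator with full ground truth (per-variant
  labels, per-patient biomarker status) for end-to-end validation of every
  stage.

## Worked example

```r
library(lymphCH)

sim    <- simulateCohort(simulationConfig(n_patients = 200, seed = 7))
cohort <- sim$cohort
cohort
#> CHCohort: 200 patients, 1139 variants
#>   compartments: BMPB=491, LN=648

parts <- partitionCohort(cohort)
summ  <- summarizePartition(parts)
sprintf("CH-positive cases: %d/%d (%.1f%%)",
        summ$n_cases_with_ch, summ$n_cases_total, 100 * summ$ch_case_fraction)
#> "CH-positive cases: 137/195 (70.3%)"
head(geneRecurrence(parts, "early"), 2)
#>     gene case_fraction
#> 5   TET2     0.4974359
#> 2 DNMT3A     0.2358974
```

About 70% of patients carry CH, dominated by `TET2` and `DNMT3A` — the
structure the partition is designed to recover. The late (lymphoma-specific)
catalog shows the C>A-rich, strand-biased spectrum:

```r
late  <- parts[parts$label %in% c("late_ln_only", "involvement") &
               !is.na(parts$context3), ]
cat96 <- buildCatalog(late, stranded = TRUE)
round(substitutionFractions(cat96)$group, 3)
#>   C>A   C>G   C>T   T>A   T>C   T>G
#> 0.543 0.036 0.353 0.021 0.024 0.024
ca <- classStrandCounts(cat96, "C>A")
strandFoldExcess(ca["forward"], ca["reverse"])
#> [1] 2.017544        # coding-strand excess; generated asymmetry is 17:5 = 2.4
```

Biomarker and CHN-free survival:

```r
calls  <- biomarkerCalls(parts, patient_ids = cohortPatients(cohort)$patient_id)
report <- chnFreeAnalysis(cohortPatients(cohort), calls)
report$logrank$p_value
#> [1] 1.279844e-21
unlist(report$cox[c("hr", "ci_low", "ci_high")])
#>       hr   ci_low  ci_high
#> 30.09949 10.31808 87.80507
```

The generating hazard ratio is 14; with the handful of biomarker-positive
patients a 200-patient cohort produces, the point estimate is variable but
the confidence interval covers the truth.

Deterministic single calls:

```r
reconstructConfusion(47, 72.7, 97.2)   # unique table: tp=8 fp=1 fn=3 tn=35
diagnosticMetrics(8, 1, 3, 35)         # 72.7 / 97.2 / 88.9 / 92.1
strandFoldExcess(17, 5)                # 2.4
rateRatio(11547, 67)                   # 172.3
```

The whole chain (ingest or simulate → partition → catalogs → signatures →
biomarker/survival) runs as one call writing a machine-readable bundle:

```r
runPipeline(list(simulation = simulationConfig(n_patients = 200)),
            out_dir = "results/run1", seed = 7)
```

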