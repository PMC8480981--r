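---
title: "Methods: clonal partition, mutational signatures and the multiple-hit TET2 biomarker"
author: "lymphCH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal partition, mutational signatures and the multiple-hit TET2 biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphCH)
```

# The scientific problem

Angioimmunoblastic T-cell lymphoma (AITL) frequently shares somatic
`TET2`/`DNMT3A` mutations with clonal hematopoiesis (CH) detectable in the
same patient's bone marrow or peripheral blood (BM/PB), pointing to a mutated
hematopoietic precursor as the cell of origin. Three analytic questions
follow, and this package implements each as a tested, reusable stage:

1. Which variants found in the BM/PB reflect CH, and which merely reflect
   contamination of the marrow by circulating lymphoma cells
   (*involvement*)?
2. Do the early (CH-associated) and late (lymphoma-restricted) mutations
   bear different mutational-process fingerprints?
3. Does a high CH mutation burden in `TET2` predict a second (concomitant)
   hematologic neoplasm, CHN?

# Clonal partition

## Tumor-burden estimation

`estimateTumorBurden()` applies an evidence hierarchy reflecting the relative
sensitivity of the clinical assays:

| tier | evidence | point estimate | interval |
|---|---|---|---|
| 1 | flow cytometry % | `flow_pct/100` | ±20% relative |
| 2 | TCRG clonality positive | 0.03 | [0.01, 0.05] (assay sensitivity) |
| 3 | lymphoma-marker VAF (`RHOA` et al.) | 2 × VAF (heterozygous) | ±50% relative |
| 4 | none | 0 | — |

Morphology is treated as corroborating only: histologic review of BM is
insensitive and lymphoma cells may lack distinctive morphology there. The
marker-VAF interval is wider than the flow interval because it rests on a
single variant's sampling noise plus the heterozygosity assumption.

## The attribution rule

A clonal heterozygous variant confined to neoplastic cells at tumor fraction
`tb` has expected VAF `tb/2`. `maxInvolvementVAF()` inflates the upper bound:

```
threshold = tb_high / 2 * (1 + tolerance),      tolerance = 0.5 by default
```

with an attribution floor of 0.001 when there is no involvement evidence.
The ×1.5 tolerance absorbs copy-number deviations and sampling noise; it is
a judgment call the source analysis left informal, so it is an explicit
argument. BM/PB variants above the threshold are CH (`CH_shared` if the
identical variant — matched by chromosome, position and alleles, not by
gene — is in the lymph node, else `CH_bmpb_only`); at or below it with an LN
counterpart they are `involvement`; LN variants with no BM/PB counterpart at
VAF ≥ 0.001 are `late_ln_only`. One rule the formal partition leaves
unstated: a BM/PB variant at or below the threshold *without* an LN
counterpart cannot be lymphoma involvement (the lymphoma lacks it), so it is
labeled `CH_bmpb_only`.

Deliberately **not** modeled: clone trees (two `DNMT3A` variants with
discordant VAFs are simply two independent labels), purity/ploidy correction,
and any absolute CH VAF floor — observed CH VAFs extend below 1%, so only the
attribution rule separates the classes.

## Post-alignment filter

`applyPostFilters()` applies the targeted-sequencing defaults: VAF ≥ 5%,
population frequency ≤ 0.01%, strand-balance ratio ≥ 0.2 (a "1:5"
minor/major read ratio read as a lower cutoff — the only reading under which
it acts as one), and, when a `func_pred` column exists, a count of damaging
in-silico predictions > 2. Rows flagged `rescued` (sites re-genotyped in the
other compartment down to VAF 0.1%) bypass the VAF cutoff; cross-compartment
rescue is what lets a 0.6% `RHOA` signal in blood count as involvement
evidence even though de novo calling would drop it.

# Catalogs and spectra

SNVs are collapsed onto the pyrimidine strand; purine-reference contexts are
reverse-complemented. The 96 contexts are ordered lexicographically
(`A[C>A]A` … `T[T>G]T`), fixed in `CONTEXTS_96`. Strand splitting relies on a
per-variant `coding_strand_ref` annotation (whether the reference strand is
the coding strand at that locus) — the package does not consult gene models;
callers or the simulator supply orientation. "Forward" means the mutated
pyrimidine lies on the coding (untranscribed) strand. Strand bias is
reported as fold *excess*, `(n_fwd − n_rev)/n_rev`, chosen because it is the
definition consistent with the reported counts-to-fold arithmetic of the
motivating analysis (17 vs 5 → 2.4).

The Ti/Tv comparison is a **paired** two-sided t test on per-sample Ti vs Tv
fractions, because the per-sample fraction is the plotted and interpreted
unit; between-group class comparisons use the Welch t test on per-case
fractions. Both choices are deliberate where the source analysis named only
"t test". Spectra can be computed on any variant subset, so restricting to
missense mutations (one figure convention) versus all SNVs (the running-text
convention) is the caller's filter, not a hidden default.

# Signature inference

`extractSignatures()` follows the bootstrapped-NMF consensus design:

1. each bootstrap resamples every sample's catalog multinomially, conserving
   its total;
2. each resample is factorized by multiplicative updates minimizing the
   generalized Kullback–Leibler divergence (the Poisson-appropriate
   objective for count catalogs; the updates provably never increase the
   objective, which `nmfKL()` records every 100 iterations so tests can
   assert it). Initialization is uniform random on [0.1, 1] from the seeded
   generator; convergence is a relative objective change ≤ `tol` (default
   1e-9) checked every 10 iterations, capped at `max_iter` = 10000;
3. all bootstrap signatures are pooled and clustered into *k* groups by
   partitioning around medoids under cosine distance; cluster means
   (renormalized) are the consensus profiles, and per-cluster mean silhouette
   widths are the stability (undefined, `NA`, at k = 1);
4. exposures are refit on the **original** catalog by non-negative least
   squares and rescaled so each sample's exposures sum to its SNV count —
   consensus profiles exist first, attribution follows.

*k* is user-supplied (the motivating analyses used 2 per extraction); no
automatic model selection is attempted, but stability plus reconstruction
residuals give the over-factorization signal (a k = 3 fit of 2-signature
data shows degraded minimum stability). The bootstrap default of 100 gives
stable consensus clusters at desk scale; tests use 15–20 bootstraps, which
already recover well-separated profiles (pairwise CCS < 0.3) at truth-CCS
> 0.99 with 20 samples × 100 mutations. Matching uses cosine correlation
similarity with ties broken toward the lowest reference index; dominance is
inclusive (a sample with exactly 50% of mutations from one signature counts
as dominated). The packaged 30-signature reference (`makeReferenceFixture()`)
is **synthetic**: an APOBEC-like profile (index 2), a smoking-like profile
(index 4), a CpCpC C>T profile (index 15) and 27 sparse decoys, all pairwise
CCS < 0.6; loading a real reference TSV via `readReferenceSignatures()` (in
either orientation) is equally supported.

# Biomarker and survival

The multiple-hit `TET2` call requires ≥2 variants in `TET2` with tier ∈
{1, 2} and VAF ≥ 15% **each**; the VAF threshold is inclusive (the criteria
statement "≥15%" is followed where a discussion passage says ">15%"; the
operator is exposed). Pathogenicity tiers are consumed as input annotation —
the package does not re-implement tiering guidelines.

Kaplan–Meier, log-rank and Cox fits are delegated to the `survival` package
with Efron tie handling (better small-sample behavior than Breslow at this
cohort scale); the test suite validates them against hand product-limit and
textbook O−E/V computations. The Cox model is univariate on biomarker
status; an optional `strata` argument supports a stratified fit (the
stratification variable behind the motivating "stratified HR" is not
documented, so unstratified is the default). Complete separation is flagged
(`monotone = TRUE`) rather than silently reported, since the Wald CI is then
unbounded. Diagnostic metrics are printed half-up at one decimal, the
convention the reconstruction oracle must invert: `reconstructConfusion()`
enumerates every non-negative 2×2 table of a given total and returns all
tables whose sensitivity and specificity round to the printed values — for
47 cases and 72.7/97.2 the solution is unique, (tp, fp, fn, tn) =
(8, 1, 3, 35), and its PPV/NPV are 88.9%/92.1%.

Direct age standardization follows `Σ_g cases_g/population_g × 100000 ×
weight_g` with weights validated to sum to 1. The cohort-level absolute
rates depend on unpublished person-time tables and are out of scope; only
the ratio of two given rates is computed. All tests are two-sided.

# The synthetic cohort: what it emulates, and what it does not

`simulationConfig()` defaults encode the target cohort conditions: CH
prevalence 0.70; BM/PB involvement 0.63; CH VAFs ~ Beta with mean 0.225 and
concentration 4 (median ≈ 0.18, support reaching sub-1% VAFs — chosen once
to match the reported mean exactly and the reported median and 0.2–51.5%
range approximately); involvement VAFs = `tb/2` × LogNormal(0, 0.2) with
tumor burden uniform on [0.01, 0.10]; 1.6 CH and 2.4 late mutations per
carrier on average; `TET2`-heavy CH genes and `RHOA`-led late genes; an
APOBEC-like CH context profile and a 0.6/0.4 smoking-like/CpCpC late
mixture; late C>A coding-strand asymmetry 17:5; CHN hazard 0.0008/month
multiplied by 14 for biomarker-positive patients, censored at 120 months;
84% of CH variants shared with the lymphoma. Involved patients carry a flow
cytometry measurement (the most objective evidence tier), exercising the
top of the TB hierarchy; the TCRG and marker-VAF tiers are exercised by unit
tests. With σ = 0.2 noise, the share of involvement VAFs within the
`tb/2 × 1.5` tolerance is `pnorm(log(1.5)/0.2)` ≈ 0.979, which is what the
property tests assert and is ample for ≥95% label recovery.

Not emulated, by design: sequencing reads and depth (VAF noise is
multiplicative log-normal, not binomial read sampling), clonal phylogenies,
copy-number events, a reference genome (contexts are drawn from signature
profiles directly; coordinates are synthetic per-gene offsets), and
covariate-dependent CHN hazards. The synthetic late-mutation spectrum is
also more concentrated in C>A/C>T than a real spectrum, because the default
mixture has only two components. Consequently, passing recovery tests shows
the pipeline's logic is correct under the stated statistical structure — it
does not certify performance on real sequencing artifacts, subclonal
copy-number distortion of VAFs, or mis-annotated strand orientation.

# Problem sizes and determinism

The test and acceptance workloads are desk-scale by choice: 200–1000-patient
simulated cohorts for partition and prevalence checks; 20 samples × 100
mutations × 20 seeds for signature recovery; 100 replicates of n = 500 per
arm for Cox recovery; 2000 and 5000 null replicates for log-rank, z- and
Welch-test calibration. Every stochastic stage takes an explicit seed and
identical seeds give bit-identical outputs, including the full
`runPipeline()` bundle. `scripts/acceptance.R` derives all sub-seeds from
its single `--seed` argument.

# Known limitations

- The partition treats each variant independently; a CH clone whose VAF
  happens to fall below the involvement threshold in an involved marrow is
  mislabeled `involvement` (the dominant term in the ~2–3% label error on
  default simulations).
- NMF consensus at very sparse per-sample counts (2–3 SNVs) yields unstable,
  partially mixed signatures — visible as low silhouette stability — which
  mirrors the difficulty of real cohorts of that sparsity.
- The biomarker's prevalence in simulated cohorts is governed by gene/tier/
  VAF draws and lands below the ~23% of the motivating cohort; survival
  recovery at the configured hazard ratio is therefore validated on
  dedicated survival simulations with fixed group sizes.
- `reconstructConfusion()` is exhaustive and exact but assumes the printed
  percentages were rounded half-up at the stated precision.
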