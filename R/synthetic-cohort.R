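## Synthetic paired-compartment cohort generator with full ground truth.
## Encodes the statistical structure the analysis assumes: ~70% CH
## prevalence dominated by TET2/DNMT3A, CH VAFs with mean 22.5%,
## involvement VAFs near 1% (tumor burden / 2), late mutations drawn from a
## smoking-like C>A-rich signature with coding-strand asymmetry, and CHN
## hazards driven by the multiple-hit TET2 biomarker.

.GENE_COORDS <- c(TET2 = "4:106000000", DNMT3A = "2:25400000",
                  ASXL1 = "20:30900000", SRSF2 = "17:74700000",
                  JAK2 = "9:5000000", RHOA = "3:49400000",
                  IDH2 = "15:90600000", PLCG1 = "20:39700000",
                  TP53 = "17:7570000", VAV1 = "19:6800000",
                  CD28 = "2:204500000")

.profileFromPeaks <- function(peaks, baseline = 0.15) {
  p <- stats::setNames(rep(baseline / 96, 96L), CONTEXTS_96)
  p[names(peaks)] <- p[names(peaks)] + peaks * (1 - baseline)
  p / sum(p)
}

#' APOBEC-like signature profile
#'
#' C>T and C>G peaks at TpCpA/TpCpT, emulating the AID/APOBEC cytidine
#' deaminase process that dominates early CH-associated mutations.
#'
#' @return Named 96-vector summing to 1.
#' @export
apobecLikeProfile <- function() {
  .profileFromPeaks(c("T[C>T]A" = 0.35, "T[C>T]T" = 0.15,
                      "T[C>G]A" = 0.25, "T[C>G]T" = 0.10,
                      "T[C>T]C" = 0.08, "T[C>G]C" = 0.07))
}

#' Smoking-like signature profile
#'
#' C>A transversions peaking at NpCpC (strongest at TpCpC), the hallmark of
#' tobacco-carcinogen mutagenesis.
#'
#' @return Named 96-vector summing to 1.
#' @export
smokingLikeProfile <- function() {
  .profileFromPeaks(c("T[C>A]C" = 0.28, "C[C>A]C" = 0.22, "A[C>A]C" = 0.14,
                      "G[C>A]C" = 0.10, "T[C>A]A" = 0.08, "C[C>A]A" = 0.06,
                      "A[C>A]A" = 0.06, "G[C>A]T" = 0.06))
}

#' CpCpC C>T signature profile
#'
#' Secondary late-mutation process enriched for C>T at CpCpC.
#'
#' @return Named 96-vector summing to 1.
#' @export
cpcLikeProfile <- function() {
  .profileFromPeaks(c("C[C>T]C" = 0.40, "C[C>T]A" = 0.15, "C[C>T]T" = 0.15,
                      "A[C>T]C" = 0.15, "G[C>T]C" = 0.15))
}

#' Simulation configuration with study defaults
#'
#' Defaults encode the cohort conditions the analysis targets: 70% CH
#' prevalence, 63% BM/PB involvement, CH VAFs with mean 22.5% (Beta,
#' concentration 4), involvement VAFs near tumor-burden/2 (~1% for typical
#' burdens), tumor burden uniform on 1-10%, 1.6 CH and 2.4 late mutations
#' per carrier on average, TET2/DNMT3A-dominated CH genes, RHOA-led late
#' genes, an APOBEC-like CH signature, a smoking-like + CpCpC late mixture
#' with 17:5 coding-strand asymmetry for C>A, and a CHN hazard ratio of 14
#' for the multiple-hit TET2 biomarker.
#'
#' @param n_patients Number of patients.
#' @param p_ch Probability a patient carries CH.
#' @param p_bmpb_involved Probability the BM/PB is involved by lymphoma.
#' @param ch_vaf_mean,ch_vaf_shape Beta mean and concentration for CH VAFs.
#' @param p_ch_shared Probability a CH variant is shared with the lymphoma.
#' @param tb_range Tumor-burden interval (uniform draw).
#' @param vaf_noise_sd Log-normal sigma of multiplicative VAF noise.
#' @param n_ch_mut_mean,n_late_mut_mean Mean mutation counts.
#' @param ch_gene_weights,late_gene_weights Named sampling weights.
#' @param p_tet2_pathogenic Probability a CH variant is tier 1/2.
#' @param ch_signature 96-profile for CH mutation contexts.
#' @param late_signature_mix List of 96-profiles for late mutations.
#' @param late_mix_weights Mixture weights for \code{late_signature_mix}.
#' @param strand_asym_forward Probability a late C>A mutation places its
#'   pyrimidine on the coding strand (default 17/22).
#' @param biomarker_hr CHN hazard ratio for biomarker-positive patients.
#' @param baseline_chn_hazard Baseline CHN hazard per month.
#' @param censor_time_months Administrative censoring time.
#' @param seed RNG seed.
#' @return Validated configuration list of class \code{simulation_config}.
#' @export
simulationConfig <- function(n_patients = 200L,
                             p_ch = 0.70,
                             p_bmpb_involved = 0.63,
                             ch_vaf_mean = 0.225,
                             ch_vaf_shape = 4,
                             p_ch_shared = 0.84,
                             tb_range = c(0.01, 0.10),
                             vaf_noise_sd = 0.2,
                             n_ch_mut_mean = 1.6,
                             n_late_mut_mean = 2.4,
                             ch_gene_weights = c(TET2 = 0.55, DNMT3A = 0.25,
                                                 ASXL1 = 0.08, SRSF2 = 0.07,
                                                 JAK2 = 0.05),
                             late_gene_weights = c(RHOA = 0.30, TET2 = 0.20,
                                                   IDH2 = 0.15, PLCG1 = 0.09,
                                                   TP53 = 0.09, VAV1 = 0.09,
                                                   CD28 = 0.08),
                             p_tet2_pathogenic = 0.8,
                             ch_signature = apobecLikeProfile(),
                             late_signature_mix = list(
                               smoking = smokingLikeProfile(),
                               cpc = cpcLikeProfile()),
                             late_mix_weights = c(0.6, 0.4),
                             strand_asym_forward = 17 / 22,
                             biomarker_hr = 14.0,
                             baseline_chn_hazard = 0.0008,
                             censor_time_months = 120,
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), p_ch = p_ch,
              p_bmpb_involved = p_bmpb_involved, ch_vaf_mean = ch_vaf_mean,
              ch_vaf_shape = ch_vaf_shape, p_ch_shared = p_ch_shared,
              tb_range = tb_range, vaf_noise_sd = vaf_noise_sd,
              n_ch_mut_mean = n_ch_mut_mean,
              n_late_mut_mean = n_late_mut_mean,
              ch_gene_weights = ch_gene_weights,
              late_gene_weights = late_gene_weights,
              p_tet2_pathogenic = p_tet2_pathogenic,
              ch_signature = ch_signature,
              late_signature_mix = late_signature_mix,
              late_mix_weights = late_mix_weights / sum(late_mix_weights),
              strand_asym_forward = strand_asym_forward,
              biomarker_hr = biomarker_hr,
              baseline_chn_hazard = baseline_chn_hazard,
              censor_time_months = censor_time_months,
              seed = as.integer(seed))
  probs <- c(cfg$p_ch, cfg$p_bmpb_involved, cfg$ch_vaf_mean, cfg$p_ch_shared,
             cfg$p_tet2_pathogenic, cfg$strand_asym_forward)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1")
  if (cfg$biomarker_hr <= 0) stop("biomarker_hr must be > 0")
  for (p in c(list(cfg$ch_signature), cfg$late_signature_mix)) {
    if (length(p) != 96L || any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop("signature profiles must be valid 96-distributions")
  }
  class(cfg) <- "simulation_config"
  cfg
}

## draw one SNV representation from a 96-profile: bin, ref-strand alleles,
## ref-strand context and coding-strand orientation
.drawSNV <- function(profile, p_forward_ca = 0.5) {
  bin <- sample(CONTEXTS_96, 1L, prob = profile)
  p5 <- substr(bin, 1L, 1L); p3 <- substr(bin, 7L, 7L)
  pyr <- substr(bin, 3L, 3L); alt_pyr <- substr(bin, 5L, 5L)
  cls <- paste0(pyr, ">", alt_pyr)
  p_fwd <- if (cls == "C>A") p_forward_ca else 0.5
  pyr_on_coding <- stats::runif(1) < p_fwd
  ref_is_pyr <- stats::runif(1) < 0.5
  ctx_pyr <- paste0(p5, pyr, p3)
  if (ref_is_pyr) {
    ref <- pyr; alt <- alt_pyr; ctx <- ctx_pyr
  } else {
    ref <- complementBase(pyr); alt <- complementBase(alt_pyr)
    ctx <- reverseComplement(ctx_pyr)
  }
  list(ref = ref, alt = alt, context3 = ctx, class = cls,
       coding_strand_ref = if (ref_is_pyr == pyr_on_coding) "same" else "opposite")
}

.drawIndel <- function(vclass) {
  if (vclass %in% c("frameshift_del", "inframe_del"))
    list(ref = "CTG", alt = "C", context3 = NA_character_,
         class = NA_character_, coding_strand_ref = "unknown")
  else
    list(ref = "C", alt = "CTG", context3 = NA_character_,
         class = NA_character_, coding_strand_ref = "unknown")
}

.rbetaMean <- function(n, mean, conc) stats::rbeta(n, mean * conc, (1 - mean) * conc)

#' Simulate a paired-compartment cohort with ground truth
#'
#' Generates, per patient: CH presence and CH mutations (genes, contexts
#' from the CH signature, BM/PB VAFs Beta-distributed around the configured
#' mean, a fraction shared with the lymphoma); BM/PB involvement with a
#' tumor burden measured by flow cytometry; late lymphoma mutations with
#' contexts from the late signature mixture and coding-strand asymmetry for
#' C>A, propagated into involved BM/PB at VAF ~ tb/2 with multiplicative
#' log-normal noise; pathogenicity tiers; the multiple-hit TET2 biomarker
#' status implied by the generated variants; and an exponential CHN time
#' whose hazard is multiplied by the configured hazard ratio for
#' biomarker-positive patients, censored administratively.
#'
#' @param config A [simulationConfig()] list.
#' @return List with \code{cohort} (a [CHCohort-class]) and \code{truth}
#'   (list: \code{variants} with per-variant \code{true_label},
#'   \code{patients} with true tumor burden and biomarker status).
#' @export
simulateCohort <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  vrows <- list(); trows <- list(); prow <- list()
  pos_counter <- 0L

  newVariant <- function(pid, compartment, gene, site, vaf, vclass, tier,
                         rescued = FALSE) {
    data.frame(patient_id = pid, compartment = compartment, gene = gene,
               chrom = site$chrom, pos = site$pos, ref = site$ref,
               alt = site$alt, context3 = site$context3,
               coding_strand_ref = site$coding_strand_ref, vclass = vclass,
               tier = tier, vaf = vaf, popfreq = NA_real_,
               strand_balance = NA_real_, rescued = rescued,
               stringsAsFactors = FALSE)
  }

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", i)
    has_ch <- stats::runif(1) < config$p_ch
    involved <- stats::runif(1) < config$p_bmpb_involved
    tb <- stats::runif(1, config$tb_range[1], config$tb_range[2])

    ## --- CH mutations ------------------------------------------------
    n_ch <- if (has_ch) 1L + stats::rpois(1L, max(0, config$n_ch_mut_mean - 1)) else 0L
    ch_bm_variants <- list()
    for (m in seq_len(n_ch)) {
      gene <- sample(names(config$ch_gene_weights), 1L,
                     prob = config$ch_gene_weights)
      vclass <- sample(c("missense", "nonsense", "frameshift_del",
                         "frameshift_ins", "splice"), 1L,
                       prob = c(0.36, 0.28, 0.14, 0.16, 0.06))
      alleles <- if (grepl("frameshift|inframe", vclass)) .drawIndel(vclass)
                 else .drawSNV(config$ch_signature)
      pos_counter <- pos_counter + 1L
      gc <- strsplit(.GENE_COORDS[[gene]], ":")[[1]]
      site <- c(alleles, list(chrom = gc[1],
                              pos = as.numeric(gc[2]) + pos_counter))
      tier <- if (stats::runif(1) < config$p_tet2_pathogenic)
        sample(1:2, 1L) else 3L
      vaf_bm <- .rbetaMean(1L, config$ch_vaf_mean, config$ch_vaf_shape)
      vaf_bm <- min(max(vaf_bm, 0.002), 1)  # observed CH VAFs reach ~0.2%
      shared <- stats::runif(1) < config$p_ch_shared
      vrows[[length(vrows) + 1L]] <-
        newVariant(pid, "BMPB", gene, site, vaf_bm, vclass, tier)
      if (shared) {
        vaf_ln <- .rbetaMean(1L, 0.30, 20)
        vrows[[length(vrows) + 1L]] <-
          newVariant(pid, "LN", gene, site, vaf_ln, vclass, tier)
      }
      trows[[length(trows) + 1L]] <-
        data.frame(patient_id = pid, chrom = site$chrom, pos = site$pos,
                   ref = site$ref, alt = site$alt, gene = gene,
                   true_label = if (shared) "CH_shared" else "CH_bmpb_only",
                   stringsAsFactors = FALSE)
      ch_bm_variants[[length(ch_bm_variants) + 1L]] <-
        data.frame(gene = gene, tier = tier, vaf = vaf_bm)
    }

    ## --- late lymphoma mutations -------------------------------------
    n_late <- stats::rpois(1L, config$n_late_mut_mean)
    for (m in seq_len(n_late)) {
      gene <- sample(names(config$late_gene_weights), 1L,
                     prob = config$late_gene_weights)
      vclass <- sample(c("missense", "nonsense", "frameshift_del"), 1L,
                       prob = c(0.752, 0.158, 0.09))
      if (grepl("frameshift", vclass)) {
        alleles <- .drawIndel(vclass)
      } else {
        comp <- sample(seq_along(config$late_signature_mix), 1L,
                       prob = config$late_mix_weights)
        alleles <- .drawSNV(config$late_signature_mix[[comp]],
                            p_forward_ca = config$strand_asym_forward)
      }
      pos_counter <- pos_counter + 1L
      gc <- strsplit(.GENE_COORDS[[gene]], ":")[[1]]
      site <- c(alleles, list(chrom = gc[1],
                              pos = as.numeric(gc[2]) + pos_counter))
      vaf_ln <- .rbetaMean(1L, 0.25, 20)
      vrows[[length(vrows) + 1L]] <-
        newVariant(pid, "LN", gene, site, vaf_ln, vclass, NA_integer_)
      prop_vaf <- if (involved)
        tb / 2 * exp(stats::rnorm(1L, 0, config$vaf_noise_sd)) else 0
      if (involved && prop_vaf >= 0.001) {
        vrows[[length(vrows) + 1L]] <-
          newVariant(pid, "BMPB", gene, site, min(prop_vaf, 1), vclass,
                     NA_integer_, rescued = prop_vaf < 0.05)
        lab <- "involvement"
      } else {
        lab <- "late_ln_only"
      }
      trows[[length(trows) + 1L]] <-
        data.frame(patient_id = pid, chrom = site$chrom, pos = site$pos,
                   ref = site$ref, alt = site$alt, gene = gene,
                   true_label = lab, stringsAsFactors = FALSE)
    }

    ## --- biomarker truth and CHN survival ----------------------------
    chdf <- if (length(ch_bm_variants)) do.call(rbind, ch_bm_variants)
            else NULL
    bm_pos <- callMultihitTET2(chdf)$positive
    hazard <- config$baseline_chn_hazard *
      ifelse(bm_pos, config$biomarker_hr, 1)
    t_chn <- stats::rexp(1L, hazard)
    event <- as.integer(t_chn <= config$censor_time_months)
    followup <- min(t_chn, config$censor_time_months)

    age <- min(85, max(30, round(stats::rnorm(1L, 62, 12))))
    prow[[length(prow) + 1L]] <- data.frame(
      patient_id = pid, diagnosis = "AITL", age_at_dx = age,
      smoking = sample(c("smoker", "nonsmoker", "unknown"), 1L,
                       prob = c(0.27, 0.70, 0.03)),
      flow_pct = if (involved) 100 * tb else NA_real_,
      tcrg = if (involved) "positive" else "negative",
      morphology_pct = NA_real_, chn_event = event,
      followup_months = followup, has_ch = has_ch, involved = involved,
      tb_true = if (involved) tb else 0, biomarker_true = bm_pos,
      stringsAsFactors = FALSE)
  }

  patients <- do.call(rbind, prow)
  variants <- if (length(vrows)) do.call(rbind, vrows) else
    normalizeVariantTable(data.frame(patient_id = character(),
                                     compartment = character(),
                                     gene = character(), chrom = character(),
                                     pos = numeric(), ref = character(),
                                     alt = character(), vaf = numeric()))
  truth_v <- if (length(trows)) do.call(rbind, trows) else NULL
  clinical_cols <- c("patient_id", "diagnosis", "age_at_dx", "smoking",
                     "flow_pct", "tcrg", "morphology_pct", "chn_event",
                     "followup_months")
  cohort <- CHCohort(patients[, clinical_cols], variants)
  list(cohort = cohort,
       truth = list(variants = truth_v,
                    patients = patients[, c("patient_id", "has_ch",
                                            "involved", "tb_true",
                                            "biomarker_true")]))
}

#' Simulate catalogs from known signatures and exposures
#'
#' Each sample's mutations are a multinomial draw from the exposure-weighted
#' mixture of the signature profiles, conserving the sample's total.
#'
#' @param signatures A [SignatureSet-class] or k x 96 profile matrix.
#' @param exposures Samples x k non-negative matrix.
#' @param seed RNG seed.
#' @return A [TrinucleotideCatalog-class].
#' @export
simulateCatalogs <- function(signatures, exposures, seed = 1L) {
  profiles <- if (is(signatures, "SignatureSet"))
    signatureProfiles(signatures) else as.matrix(signatures)
  exposures <- as.matrix(exposures)
  if (any(exposures < 0)) stop("exposures must be non-negative")
  stopifnot(ncol(exposures) == nrow(profiles))
  set.seed(as.integer(seed))
  n <- nrow(exposures)
  counts <- matrix(0L, n, 96L, dimnames = list(
    if (is.null(rownames(exposures))) sprintf("S%03d", seq_len(n))
    else rownames(exposures), CONTEXTS_96))
  for (i in seq_len(n)) {
    tot <- round(sum(exposures[i, ]))
    if (tot == 0) next
    mix <- as.numeric(t(profiles) %*% (exposures[i, ] / sum(exposures[i, ])))
    counts[i, ] <- as.integer(stats::rmultinom(1L, tot, mix))
  }
  new("TrinucleotideCatalog", counts = counts,
      strandedCounts = matrix(0L, 0L, 192L,
                              dimnames = list(NULL, CONTEXTS_192)))
}

#' Synthetic 30-signature reference set
#'
#' Builds a synthetic stand-in for a 30-signature reference matrix: an
#' APOBEC-like profile (index 2), a smoking-like profile (index 4), a CpCpC
#' C>T profile (index 15) and 27 random sparse decoys, with all distinct
#' pairs below cosine similarity 0.6.
#'
#' @param seed RNG seed.
#' @return A [SignatureSet-class] of 30 profiles named
#'   \code{Signature.1 ... Signature.30}.
#' @export
makeReferenceFixture <- function(seed = 42L) {
  set.seed(as.integer(seed))
  fixed <- list(`2` = apobecLikeProfile(), `4` = smokingLikeProfile(),
                `15` = cpcLikeProfile())
  profiles <- matrix(NA_real_, 30L, 96L,
                     dimnames = list(paste0("Signature.", 1:30), CONTEXTS_96))
  for (nm in names(fixed)) profiles[as.integer(nm), ] <- fixed[[nm]]
  accepted <- do.call(rbind, fixed)
  for (i in which(is.na(profiles[, 1L]))) {
    for (attempt in 1:500) {
      peaks <- sample(CONTEXTS_96, 6L)
      w <- stats::rgamma(6L, 1.5)
      cand <- .profileFromPeaks(stats::setNames(w / sum(w), peaks),
                                baseline = 0.10)
      if (all(cosineSimilarityMatrix(rbind(cand), accepted) < 0.6)) break
      if (attempt == 500) stop("could not place a decoy signature")
    }
    profiles[i, ] <- cand
    accepted <- rbind(accepted, cand)
  }
  SignatureSet(profiles)
}

#' Write a simulated cohort as the package's on-disk dialects
#'
#' Writes \code{variants.tsv}, \code{clinical.csv} and, when ground truth is
#' supplied, \code{ground_truth.tsv}.
#'
#' @param cohort A [CHCohort-class].
#' @param dir Output directory (created if needed).
#' @param truth Optional truth list from [simulateCohort()].
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeVariantTable(cohortVariants(cohort), file.path(dir, "variants.tsv"))
  utils::write.csv(cohortPatients(cohort), file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  if (!is.null(truth))
    utils::write.table(truth$variants, file.path(dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
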