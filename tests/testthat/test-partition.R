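test_that("tumor-burden hierarchy follows flow > TCRG > marker VAF", {
  rec <- list(patient_id = "P1", flow_pct = 8, tcrg = "positive")
  tb <- estimateTumorBurden(rec)
  expect_equal(tb@tb, 0.08)
  expect_equal(tb@method, "flow")

  rec <- list(patient_id = "P1", flow_pct = NA, tcrg = "positive")
  tb <- estimateTumorBurden(rec)
  expect_equal(tb@tb, 0.03)
  expect_equal(c(tb@tb_low, tb@tb_high), c(0.01, 0.05))
  expect_equal(tb@method, "tcrg")

  rec <- list(patient_id = "P1", flow_pct = NA, tcrg = "negative")
  bm <- data.frame(gene = "RHOA", vaf = 0.005)
  tb <- estimateTumorBurden(rec, bm)
  expect_equal(tb@tb, 0.01)
  expect_equal(tb@method, "marker_vaf")

  tb <- estimateTumorBurden(rec, data.frame(gene = "TET2", vaf = 0.2))
  expect_equal(tb@method, "none")
  expect_equal(tb@tb, 0)

  expect_error(estimateTumorBurden(list(patient_id = "P1", flow_pct = 120)),
               "flow_pct")
})

test_that("involvement VAF bound is the inflated heterozygous limit", {
  expect_equal(maxInvolvementVAF(tbEstimate(0.04, "tcrg", 0.01, 0.05)), 0.0375)
  expect_equal(maxInvolvementVAF(tbEstimate(0, "none")), 0.001)
  expect_equal(maxInvolvementVAF(tbEstimate(1, "flow", 1, 1), tolerance = 0),
               0.5)
})

test_that("variants partition into the four classes", {
  tb <- tbEstimate(0.02, "flow", 0.016, 0.024)
  ln <- data.frame(patient_id = "P1", gene = c("TET2", "RHOA", "IDH2"),
                   chrom = "1", pos = 1:3, ref = "C", alt = "T",
                   vaf = c(0.35, 0.20, 0.30), stringsAsFactors = FALSE)
  bm <- data.frame(patient_id = "P1", gene = c("TET2", "RHOA", "DNMT3A"),
                   chrom = "1", pos = c(1, 2, 9), ref = "C", alt = "T",
                   vaf = c(0.30, 0.006, 0.25), stringsAsFactors = FALSE)
  p <- partitionVariants(ln, bm, tb)
  lab <- setNames(p$label, p$gene)
  expect_equal(lab[["TET2"]], "CH_shared")      # high-VAF, in both
  expect_equal(lab[["RHOA"]], "involvement")    # ~tb/2, lymphoma marker
  expect_equal(lab[["IDH2"]], "late_ln_only")   # LN-exclusive
  expect_equal(lab[["DNMT3A"]], "CH_bmpb_only") # BM-only, high VAF
  ## exhaustiveness: one row per input variant
  expect_equal(nrow(p), 4L)
  expect_equal(p$vaf_ln[p$gene == "TET2"], 0.35)
  expect_equal(p$vaf_bmpb[p$gene == "TET2"], 0.30)

  dup <- rbind(bm, bm[1, ])
  expect_error(partitionVariants(ln, dup, tb), "duplicate")
})

test_that("raising tumor burden never converts involvement to CH", {
  ln <- data.frame(patient_id = "P1", gene = "RHOA", chrom = "1", pos = 1,
                   ref = "C", alt = "T", vaf = 0.2)
  bm <- ln; bm$vaf <- 0.015
  labels <- vapply(c(0.01, 0.03, 0.05, 0.10, 0.5), function(t) {
    partitionVariants(ln, bm, tbEstimate(t, "flow", 0.8 * t, 1.2 * t))$label
  }, character(1))
  ## once involvement, stays involvement as tb grows
  first_inv <- match("involvement", labels)
  expect_false(is.na(first_inv))
  expect_true(all(labels[first_inv:length(labels)] == "involvement"))
})

test_that("partition summary conserves counts and tracks ground truth", {
  sim <- simulateCohort(simulationConfig(n_patients = 60L, seed = 21L))
  parts <- partitionCohort(sim$cohort)
  s <- summarizePartition(parts, 60L)
  expect_equal(s$n_shared + s$n_bmpb_only, s$n_bmpb_variants)
  n_bmpb_total <- sum(cohortVariants(sim$cohort)$compartment == "BMPB")
  expect_equal(s$n_bmpb_variants + s$n_involvement, n_bmpb_total)
  expect_true(s$n_cases_with_ch <= s$n_cases_total)

  ## summary tallies equal independent ground-truth tallies when the labels
  ## themselves are the true ones
  key <- function(df) paste(df$patient_id, df$chrom, df$pos, df$ref, df$alt)
  tv <- sim$truth$variants
  idx <- match(key(parts), key(tv))
  true_parts <- parts[!is.na(idx), ]
  true_parts$label <- tv$true_label[idx[!is.na(idx)]]
  st <- summarizePartition(true_parts, 60L)
  expect_equal(st$n_shared, sum(tv$true_label == "CH_shared"))
  expect_equal(st$n_bmpb_only, sum(tv$true_label == "CH_bmpb_only"))
  expect_equal(st$n_cases_with_ch, length(unique(
    tv$patient_id[grepl("^CH", tv$true_label)])))
})

test_that("summarizePartition handles an all-LN-only patient", {
  parts <- data.frame(patient_id = "P1", gene = "IDH2", label = "late_ln_only",
                      vaf_ln = 0.3, vaf_bmpb = NA_real_)
  s <- summarizePartition(parts)
  expect_equal(s$n_cases_with_ch, 0L)
  expect_true(is.na(s$mean_vaf_ch))
})

test_that("gene recurrence counts case fractions per label", {
  parts <- data.frame(
    patient_id = c("P1", "P1", "P2", "P3"),
    gene = c("RHOA", "TET2", "RHOA", "TET2"),
    label = c("late_ln_only", "CH_shared", "involvement", "CH_shared"),
    vaf_ln = 0.2, vaf_bmpb = c(NA, 0.3, 0.01, 0.25))
  late <- geneRecurrence(parts, "late")
  expect_equal(late$case_fraction[late$gene == "RHOA"], 2 / 3,
               tolerance = 1e-12)
  early <- geneRecurrence(parts, "early")
  expect_equal(early$case_fraction[early$gene == "TET2"], 2 / 3,
               tolerance = 1e-12)
  expect_equal(nrow(geneRecurrence(parts[0, ], "early")), 0L)
  expect_error(geneRecurrence(parts, "weird"), "unknown")
})

test_that("labels are >=95% accurate under paper-like VAF separation", {
  ## CH VAFs >= 0.10 versus tumor burden <= 0.06: clean separation
  cfg <- simulationConfig(n_patients = 120L, tb_range = c(0.01, 0.06),
                          seed = 33L)
  sim <- simulateCohort(cfg)
  parts <- partitionCohort(sim$cohort)
  acc <- partitionAccuracy(parts, sim$truth$variants)
  expect_gte(acc, 0.95)
})
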