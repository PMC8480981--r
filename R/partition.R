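## Tumor-burden estimation and the early/late clonal partition of paired
## lymph-node and bone-marrow/blood variants.

#' Estimate tumor burden in a BM/PB sample
#'
#' Applies the evidence hierarchy: (1) flow cytometry percentage when
#' available (interval +/- 20% relative); (2) otherwise a positive TCRG
#' clonality result maps to the assay's analytic sensitivity window of
#' 1-5% (point estimate 3%); (3) otherwise, a lymphoma-marker variant
#' (default gene RHOA, e.g. the p.G17V hotspot) detected in BM/PB sets
#' tb = 2 x its VAF under a heterozygous assumption (interval +/- 50%
#' relative); (4) otherwise tb = 0. Morphology corroborates but never sets
#' the estimate.
#'
#' @param record One-row clinical data.frame (or list) with \code{patient_id},
#'   \code{flow_pct}, \code{tcrg}.
#' @param bmpb_variants Variant data.frame restricted to this patient's BM/PB
#'   compartment (may be NULL).
#' @param marker_genes Genes treated as lymphoma markers (default "RHOA").
#' @return A [TumorBurdenEstimate-class].
#' @export
estimateTumorBurden <- function(record, bmpb_variants = NULL,
                                marker_genes = "RHOA") {
  pid <- as.character(record$patient_id)
  flow <- record$flow_pct
  if (!is.null(flow) && !is.na(flow)) {
    if (flow < 0 || flow > 100) stop("flow_pct outside [0,100]")
    tb <- flow / 100
    return(new("TumorBurdenEstimate", patient_id = pid, tb = tb,
               method = "flow", tb_low = tb * 0.8,
               tb_high = min(1, tb * 1.2)))
  }
  tcrg <- record$tcrg
  if (!is.null(tcrg) && !is.na(tcrg) && tcrg == "positive") {
    return(new("TumorBurdenEstimate", patient_id = pid, tb = 0.03,
               method = "tcrg", tb_low = 0.01, tb_high = 0.05))
  }
  if (!is.null(bmpb_variants) && nrow(bmpb_variants) > 0) {
    hit <- bmpb_variants[bmpb_variants$gene %in% marker_genes, , drop = FALSE]
    if (nrow(hit) > 0) {
      tb <- min(1, 2 * max(hit$vaf))
      return(new("TumorBurdenEstimate", patient_id = pid, tb = tb,
                 method = "marker_vaf", tb_low = tb * 0.5,
                 tb_high = min(1, tb * 1.5)))
    }
  }
  new("TumorBurdenEstimate", patient_id = pid, tb = 0, method = "none",
      tb_low = 0, tb_high = 0)
}

#' Maximum VAF attributable to lymphoma involvement
#'
#' A clonal heterozygous variant confined to neoplastic cells at tumor
#' fraction tb has expected VAF tb/2; the tolerance inflates this bound to
#' absorb copy-number and sampling noise. When no involvement evidence
#' exists (\code{method = "none"}) the attribution floor 0.001 is returned.
#'
#' @param tb A [TumorBurdenEstimate-class].
#' @param tolerance Relative tolerance on the heterozygous bound (default 0.5).
#' @return Numeric VAF threshold.
#' @examples
#' tb <- new("TumorBurdenEstimate", patient_id = "p", tb = 0.03,
#'           method = "tcrg", tb_low = 0.01, tb_high = 0.05)
#' maxInvolvementVAF(tb)  # 0.05/2 * 1.5 = 0.0375
#' @export
maxInvolvementVAF <- function(tb, tolerance = 0.5) {
  stopifnot(is(tb, "TumorBurdenEstimate"), tolerance >= 0)
  if (tb@method == "none") return(0.001)
  max(tb@tb_high / 2 * (1 + tolerance), 0.001)
}

#' Partition one patient's variants into early/late classes
#'
#' Matches variants across compartments by exact site and alleles
#' (\code{chrom, pos, ref, alt}) and labels every variant exactly once:
#' \itemize{
#'   \item BM/PB variant with VAF above [maxInvolvementVAF()] cannot be
#'     explained by lymphoma involvement alone: \code{CH_shared} if also in
#'     the LN, else \code{CH_bmpb_only};
#'   \item BM/PB variant at or below the threshold with an LN counterpart:
#'     \code{involvement} (the BM/PB signal is the lymphoma itself);
#'   \item BM/PB variant at or below the threshold without an LN
#'     counterpart: \code{CH_bmpb_only} (it cannot be involvement if the
#'     lymphoma lacks it);
#'   \item LN variant with no BM/PB counterpart at or above
#'     \code{rescue_floor}: \code{late_ln_only}.
#' }
#' Matched pairs produce a single row carrying both VAFs.
#'
#' @param ln_variants,bmpb_variants Variant data.frames for one patient.
#' @param tb A [TumorBurdenEstimate-class] for the BM/PB sample.
#' @param tolerance Passed to [maxInvolvementVAF()].
#' @param rescue_floor Minimum VAF at which a site counts as present in
#'   BM/PB when re-genotyping an LN site (default 0.001).
#' @return data.frame with columns \code{patient_id, gene, chrom, pos, ref,
#'   alt, context3, coding_strand_ref, vclass, tier, label, vaf_ln,
#'   vaf_bmpb}.
#' @export
partitionVariants <- function(ln_variants, bmpb_variants, tb,
                              tolerance = 0.5, rescue_floor = 0.001) {
  stopifnot(is(tb, "TumorBurdenEstimate"))
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  empty_v <- function() data.frame(patient_id = character(), gene = character(),
                                   chrom = character(), pos = numeric(),
                                   ref = character(), alt = character(),
                                   context3 = character(),
                                   coding_strand_ref = character(),
                                   vclass = character(), tier = integer(),
                                   vaf = numeric())
  if (is.null(ln_variants) || nrow(ln_variants) == 0L) ln_variants <- empty_v()
  if (is.null(bmpb_variants) || nrow(bmpb_variants) == 0L) bmpb_variants <- empty_v()
  kln <- key(ln_variants); kbm <- key(bmpb_variants)
  if (anyDuplicated(kln) || anyDuplicated(kbm))
    stop("duplicate (site, compartment) variant rows")

  ## ignore BM/PB signal below the rescue floor entirely
  seen_bm <- bmpb_variants$vaf >= rescue_floor
  thr <- maxInvolvementVAF(tb, tolerance)

  rows <- list()
  take <- function(df, i, lab, vaf_ln, vaf_bmpb) {
    data.frame(patient_id = as.character(df$patient_id[i]),
               gene = df$gene[i], chrom = df$chrom[i], pos = df$pos[i],
               ref = df$ref[i], alt = df$alt[i],
               context3 = if ("context3" %in% names(df)) df$context3[i] else NA_character_,
               coding_strand_ref = if ("coding_strand_ref" %in% names(df))
                 df$coding_strand_ref[i] else "unknown",
               vclass = if ("vclass" %in% names(df)) df$vclass[i] else "other",
               tier = if ("tier" %in% names(df)) df$tier[i] else NA_integer_,
               label = lab, vaf_ln = vaf_ln, vaf_bmpb = vaf_bmpb,
               stringsAsFactors = FALSE)
  }

  matched_ln <- logical(nrow(ln_variants))
  for (i in seq_len(nrow(bmpb_variants))) {
    if (!seen_bm[i]) next
    j <- match(kbm[i], kln)
    in_ln <- !is.na(j)
    if (in_ln) matched_ln[j] <- TRUE
    v <- bmpb_variants$vaf[i]
    lab <- if (v > thr) {
      if (in_ln) "CH_shared" else "CH_bmpb_only"
    } else {
      if (in_ln) "involvement" else "CH_bmpb_only"
    }
    src <- if (in_ln) ln_variants else bmpb_variants
    si <- if (in_ln) j else i
    rows[[length(rows) + 1L]] <-
      take(src, si, lab, if (in_ln) ln_variants$vaf[j] else NA_real_, v)
  }
  for (j in seq_len(nrow(ln_variants))) {
    if (matched_ln[j]) next
    rows[[length(rows) + 1L]] <-
      take(ln_variants, j, "late_ln_only", ln_variants$vaf[j], NA_real_)
  }
  if (!length(rows))
    return(cbind(empty_v()[, setdiff(names(empty_v()), "vaf")],
                 data.frame(label = character(), vaf_ln = numeric(),
                            vaf_bmpb = numeric())))
  do.call(rbind, rows)
}

#' Partition every patient in a cohort
#'
#' Estimates tumor burden per patient (via [estimateTumorBurden()]) and
#' applies [partitionVariants()] to each patient's paired variant lists.
#'
#' @param cohort A [CHCohort-class].
#' @param tolerance,rescue_floor Passed through to [partitionVariants()].
#' @param marker_genes Passed to [estimateTumorBurden()].
#' @return data.frame of partitioned variants across all patients.
#' @export
partitionCohort <- function(cohort, tolerance = 0.5, rescue_floor = 0.001,
                            marker_genes = "RHOA") {
  pats <- cohortPatients(cohort); vars <- cohortVariants(cohort)
  out <- lapply(seq_len(nrow(pats)), function(i) {
    pid <- pats$patient_id[i]
    pv <- vars[vars$patient_id == pid, , drop = FALSE]
    ln <- pv[pv$compartment == "LN", , drop = FALSE]
    bm <- pv[pv$compartment == "BMPB", , drop = FALSE]
    tb <- estimateTumorBurden(pats[i, ], bm, marker_genes)
    partitionVariants(ln, bm, tb, tolerance, rescue_floor)
  })
  do.call(rbind, out)
}

#' Summarize a variant partition
#'
#' Counts shared / BM-PB-specific / LN-only variants, the fraction of cases
#' carrying at least one CH variant, and VAF summaries of CH-associated
#' (VAF-CH) and involvement-attributed (VAF-inv) variants.
#'
#' @param partitions data.frame from [partitionCohort()] (or rbind of
#'   per-patient [partitionVariants()] results), with \code{patient_id}.
#' @param n_cases_total Total number of cases; defaults to the number of
#'   distinct patients in \code{partitions}.
#' @return Named list; \code{n_bmpb_variants} counts CH-classified BM/PB
#'   variants, so \code{n_shared + n_bmpb_only == n_bmpb_variants}.
#' @export
summarizePartition <- function(partitions, n_cases_total = NULL) {
  stopifnot(nrow(partitions) >= 1L)
  if (is.null(n_cases_total))
    n_cases_total <- length(unique(partitions$patient_id))
  ch <- partitions$label %in% c("CH_shared", "CH_bmpb_only")
  ch_cases <- unique(partitions$patient_id[ch])
  vaf_ch <- partitions$vaf_bmpb[ch]
  vaf_inv <- partitions$vaf_bmpb[partitions$label == "involvement"]
  list(n_bmpb_variants = sum(ch),
       n_shared = sum(partitions$label == "CH_shared"),
       n_bmpb_only = sum(partitions$label == "CH_bmpb_only"),
       n_ln_only = sum(partitions$label == "late_ln_only"),
       n_involvement = sum(partitions$label == "involvement"),
       n_cases_with_ch = length(ch_cases),
       n_cases_total = n_cases_total,
       ch_case_fraction = length(ch_cases) / n_cases_total,
       mean_vaf_ch = if (length(vaf_ch)) mean(vaf_ch) else NA_real_,
       median_vaf_ch = if (length(vaf_ch)) stats::median(vaf_ch) else NA_real_,
       mean_vaf_inv = if (length(vaf_inv)) mean(vaf_inv) else NA_real_)
}

#' Per-gene recurrence among partition labels
#'
#' Fraction of cases carrying at least one variant of the requested label.
#' The aggregate labels \code{"early"} (CH_shared + CH_bmpb_only) and
#' \code{"late"} (late_ln_only + involvement, i.e. lymphoma-restricted
#' variants) are also accepted.
#'
#' @param partitions data.frame as in [summarizePartition()].
#' @param label One of the four partition labels, \code{"early"} or
#'   \code{"late"}.
#' @param n_cases_total Denominator; defaults to distinct patients present.
#' @return data.frame with \code{gene} and \code{case_fraction}, sorted
#'   decreasing.
#' @export
geneRecurrence <- function(partitions, label, n_cases_total = NULL) {
  labs <- switch(label,
                 early = c("CH_shared", "CH_bmpb_only"),
                 late = c("late_ln_only", "involvement"),
                 label)
  if (!all(labs %in% c("CH_shared", "CH_bmpb_only", "involvement", "late_ln_only")))
    stop("unknown partition label: ", label)
  if (is.null(n_cases_total))
    n_cases_total <- length(unique(partitions$patient_id))
  sel <- partitions[partitions$label %in% labs, , drop = FALSE]
  if (nrow(sel) == 0L)
    return(data.frame(gene = character(), case_fraction = numeric()))
  tab <- tapply(sel$patient_id, sel$gene, function(p) length(unique(p)))
  out <- data.frame(gene = names(tab),
                    case_fraction = as.numeric(tab) / n_cases_total)
  out[order(-out$case_fraction, out$gene), , drop = FALSE]
}
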