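## Multiple-hit TET2 biomarker and concomitant-hematologic-neoplasm (CHN)
## free survival: KM / log-rank / Cox via the survival package, diagnostic
## metrics, and the brute-force confusion-table reconstruction oracle.

#' Multiple-hit TET2 biomarker call for one patient
#'
#' Positive when the CH identified in BM/PB harbors at least
#' \code{min_hits} pathogenic (tier 1/2) variants in \code{gene}, each with
#' VAF at or above \code{vaf_min} (inclusive 15% by default).
#'
#' @param ch_variants data.frame of one patient's CH-labeled BM/PB variants
#'   with columns \code{gene}, \code{tier} and a VAF column (\code{vaf} or
#'   \code{vaf_bmpb}).
#' @param vaf_min Minimum VAF per qualifying variant (default 0.15).
#' @param min_hits Minimum number of qualifying variants (default 2).
#' @param gene Gene symbol (default "TET2").
#' @param tiers Pathogenic tiers (default 1 and 2).
#' @return List: \code{positive}, \code{n_qualifying}, \code{qualifying_vafs}.
#' @export
callMultihitTET2 <- function(ch_variants, vaf_min = 0.15, min_hits = 2L,
                             gene = "TET2", tiers = c(1L, 2L)) {
  if (is.null(ch_variants) || nrow(ch_variants) == 0L)
    return(list(positive = FALSE, n_qualifying = 0L,
                qualifying_vafs = numeric(0)))
  vaf <- if ("vaf" %in% names(ch_variants)) ch_variants$vaf
         else ch_variants$vaf_bmpb
  qual <- ch_variants$gene == gene &
    !is.na(ch_variants$tier) & ch_variants$tier %in% tiers &
    !is.na(vaf) & vaf >= vaf_min
  list(positive = sum(qual) >= min_hits,
       n_qualifying = sum(qual),
       qualifying_vafs = vaf[qual])
}

#' Biomarker calls for every patient in a partition
#'
#' Applies [callMultihitTET2()] to each patient's CH-labeled variants.
#'
#' @param partitions data.frame from [partitionCohort()].
#' @param patient_ids Patients to call (default: all in \code{partitions});
#'   patients without CH variants are negative.
#' @param ... Passed to [callMultihitTET2()].
#' @return data.frame with \code{patient_id}, \code{positive},
#'   \code{n_qualifying}.
#' @export
biomarkerCalls <- function(partitions, patient_ids = NULL, ...) {
  if (is.null(patient_ids)) patient_ids <- unique(partitions$patient_id)
  ch <- partitions[partitions$label %in% c("CH_shared", "CH_bmpb_only"), ,
                   drop = FALSE]
  out <- lapply(patient_ids, function(p) {
    call <- callMultihitTET2(ch[ch$patient_id == p, , drop = FALSE], ...)
    data.frame(patient_id = p, positive = call$positive,
               n_qualifying = call$n_qualifying, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Follow-up times (months, >= 0).
#' @param event Event indicator (1 = CHN occurrence, 0 = censored).
#' @return data.frame with \code{time}, \code{survival}, \code{at_risk} at
#'   each observed event/censoring time; survival starts at 1 and is
#'   non-increasing.
#' @export
kmEstimate <- function(time, event) {
  if (any(time < 0)) stop("negative survival time")
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, survival = fit$surv, at_risk = fit$n.risk)
}

#' Two-group log-rank test
#'
#' @param time,event Survival data.
#' @param group Two-level grouping vector.
#' @return List: \code{chi2}, \code{p_value} (1 df). With zero events,
#'   \code{p_value = 1} with a warning.
#' @export
logrankTest <- function(time, event, group) {
  if (any(time < 0)) stop("negative survival time")
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("exactly two groups required")
  if (sum(event) == 0) {
    warning("no events observed; log-rank test degenerate (p = 1)")
    return(list(chi2 = 0, p_value = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chi2 = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Cox hazard ratio for a binary covariate
#'
#' Partial-likelihood fit with Efron tie handling and a Wald 95% CI on the
#' log scale. Complete separation of events (all events in one group) is
#' flagged as a monotone likelihood; the CI is then unreliable/unbounded.
#'
#' @param time,event Survival data (at least one event).
#' @param group Binary covariate; the hazard ratio is for the second level
#'   (e.g. biomarker-positive) versus the first.
#' @param strata Optional stratification factor for a stratified fit.
#' @return List: \code{hr}, \code{ci_low}, \code{ci_high}, \code{p_value},
#'   \code{monotone} (separation flag).
#' @export
coxHRBinary <- function(time, event, group, strata = NULL) {
  if (sum(event) == 0) stop("no events in data")
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("exactly two groups required")
  ev_by <- tapply(event, group, sum)
  monotone <- any(ev_by == 0)
  fitOnce <- function() {
    if (is.null(strata))
      survival::coxph(survival::Surv(time, event) ~ group, ties = "efron")
    else
      survival::coxph(survival::Surv(time, event) ~ group +
                        survival::strata(strata), ties = "efron")
  }
  ## under separation the optimizer's own convergence chatter is expected
  fit <- if (monotone) suppressWarnings(fitOnce()) else fitOnce()
  beta <- unname(stats::coef(fit)[1L])
  se <- sqrt(stats::vcov(fit)[1L, 1L])
  if (monotone)
    warning("all events in one group: monotone likelihood, CI unbounded")
  list(hr = exp(beta),
       ci_low = exp(beta - 1.959964 * se),
       ci_high = exp(beta + 1.959964 * se),
       p_value = unname(summary(fit)$coefficients[1L, "Pr(>|z|)"]),
       monotone = monotone)
}

#' Diagnostic metrics from a 2x2 confusion table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp) and NPV
#' tn/(tn+fn), reported as percentages rounded half-up to one decimal.
#' A zero denominator yields \code{NA} for that metric.
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @return Named list of percentages.
#' @examples
#' diagnosticMetrics(8, 1, 3, 35)  # 72.7 / 97.2 / 88.9 / 92.1
#' @export
diagnosticMetrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  pct <- function(num, den) if (den == 0) NA_real_ else
    roundHalfUp(100 * num / den, 1L)
  list(sensitivity = pct(tp, tp + fn), specificity = pct(tn, tn + fp),
       ppv = pct(tp, tp + fp), npv = pct(tn, tn + fn))
}

#' Reconstruct confusion tables from printed sensitivity/specificity
#'
#' Exhaustively enumerates all non-negative integer 2x2 tables with
#' \code{tp+fp+fn+tn = n_total} whose sensitivity and specificity round
#' (half-up, to \code{decimals} places) to the given percentages.
#'
#' @param n_total Total cases (<= 10000).
#' @param sens_pct,spec_pct Printed percentages.
#' @param decimals Rounding precision of the printed values (default 1).
#' @return data.frame of solutions with columns \code{tp, fp, fn, tn} (0
#'   rows when impossible).
#' @export
reconstructConfusion <- function(n_total, sens_pct, spec_pct, decimals = 1L) {
  stopifnot(n_total >= 1, n_total <= 10000)
  sols <- list()
  for (pos in 0:n_total) {      # pos = tp + fn (condition-positive cases)
    neg <- n_total - pos
    tps <- if (pos == 0) integer(0) else
      (0:pos)[roundHalfUp(100 * (0:pos) / pos, decimals) == sens_pct]
    tns <- if (neg == 0) integer(0) else
      (0:neg)[roundHalfUp(100 * (0:neg) / neg, decimals) == spec_pct]
    if (!length(tps) || !length(tns)) next
    grid <- expand.grid(tp = tps, tn = tns)
    grid$fn <- pos - grid$tp
    grid$fp <- neg - grid$tn
    sols[[length(sols) + 1L]] <- grid[, c("tp", "fp", "fn", "tn")]
  }
  if (!length(sols))
    return(data.frame(tp = integer(), fp = integer(),
                      fn = integer(), tn = integer()))
  out <- do.call(rbind, sols)
  rownames(out) <- NULL
  out
}

#' CHN-free survival analysis of a biomarker
#'
#' Groups patients by biomarker status, estimates per-group KM curves, runs
#' the log-rank test and a binary-covariate Cox model, and computes
#' diagnostic metrics treating CHN occurrence as the condition and the
#' biomarker as the test. With a single group the survival comparisons are
#' skipped with a warning.
#'
#' @param clinical data.frame with \code{patient_id}, \code{followup_months},
#'   \code{chn_event}.
#' @param calls data.frame from [biomarkerCalls()].
#' @return List: \code{records}, \code{km} (per group), \code{logrank},
#'   \code{cox}, \code{confusion}, \code{metrics}.
#' @export
chnFreeAnalysis <- function(clinical, calls) {
  idx <- match(clinical$patient_id, calls$patient_id)
  if (anyNA(idx)) stop("every patient needs a biomarker call")
  rec <- data.frame(patient_id = clinical$patient_id,
                    time_months = clinical$followup_months,
                    event = clinical$chn_event,
                    group = ifelse(calls$positive[idx],
                                   "high_burden", "low_or_absent"),
                    stringsAsFactors = FALSE)
  tp <- sum(rec$event == 1 & rec$group == "high_burden")
  fp <- sum(rec$event == 0 & rec$group == "high_burden")
  fn <- sum(rec$event == 1 & rec$group == "low_or_absent")
  tn <- sum(rec$event == 0 & rec$group == "low_or_absent")
  out <- list(records = rec,
              km = lapply(split(rec, rec$group), function(g)
                kmEstimate(g$time_months, g$event)),
              confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
              metrics = diagnosticMetrics(tp, fp, fn, tn))
  if (length(unique(rec$group)) < 2L) {
    warning("single biomarker group: survival comparisons skipped")
    out$logrank <- NULL; out$cox <- NULL
    return(out)
  }
  grp <- factor(rec$group, levels = c("low_or_absent", "high_burden"))
  out$logrank <- logrankTest(rec$time_months, rec$event, grp)
  out$cox <- coxHRBinary(rec$time_months, rec$event, grp)
  out
}
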