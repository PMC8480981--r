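## 96/192-context catalogs and substitution-spectrum statistics.

#' Build a trinucleotide catalog from variants
#'
#' Bins each SNV (single-base ref and alt) into the 96 pyrimidine-collapsed
#' trinucleotide contexts; indels and other non-SNVs are excluded. Contexts
#' of purine-reference SNVs are reverse-complemented before binning. With
#' \code{stranded = TRUE}, counts are additionally split by transcriptional
#' strand: \code{fwd} when the mutated pyrimidine lies on the coding
#' (untranscribed) strand, \code{rev} when on the transcribed strand,
#' resolved from each variant's \code{coding_strand_ref} annotation
#' (\code{unknown} contributes to the unstranded bins only).
#'
#' @param variants Variant data.frame with \code{context3} present for SNVs.
#' @param stranded Build the 192-bin strand-split matrix as well?
#' @param sample_by Column defining catalog samples (default
#'   \code{"patient_id"}).
#' @return A [TrinucleotideCatalog-class].
#' @export
buildCatalog <- function(variants, stranded = FALSE, sample_by = "patient_id") {
  is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref %in% .BASES & variants$alt %in% .BASES
  v <- variants[is_snv, , drop = FALSE]
  samples <- sort(unique(as.character(variants[[sample_by]])))
  counts <- matrix(0L, nrow = length(samples), ncol = 96L,
                   dimnames = list(samples, CONTEXTS_96))
  strc <- matrix(0L, nrow = 0L, ncol = 192L,
                 dimnames = list(NULL, CONTEXTS_192))
  if (stranded)
    strc <- matrix(0L, nrow = length(samples), ncol = 192L,
                   dimnames = list(samples, CONTEXTS_192))
  if (nrow(v) > 0) {
    if (anyNA(v$context3))
      stop("SNV row(s) lack context3; cannot build catalog")
    bins <- contextBin(v$context3, v$ref, v$alt)
    sid <- as.character(v[[sample_by]])
    for (i in seq_len(nrow(v))) {
      counts[sid[i], bins[i]] <- counts[sid[i], bins[i]] + 1L
      if (stranded) {
        cs <- v$coding_strand_ref[i]
        if (cs %in% c("same", "opposite")) {
          ref_is_pyr <- v$ref[i] %in% c("C", "T")
          ## pyrimidine sits on the coding strand iff its strand is coding
          pyr_on_coding <- (ref_is_pyr && cs == "same") ||
            (!ref_is_pyr && cs == "opposite")
          lab <- paste0(bins[i], if (pyr_on_coding) ":fwd" else ":rev")
          strc[sid[i], lab] <- strc[sid[i], lab] + 1L
        }
      }
    }
  }
  new("TrinucleotideCatalog", counts = counts, strandedCounts = strc)
}

#' Six-class substitution fractions
#'
#' Pooled and per-sample fractions of the six substitution classes.
#'
#' @param x A [TrinucleotideCatalog-class] or a variant data.frame (from
#'   which a catalog is built).
#' @param ... Passed to [buildCatalog()] when \code{x} is a data.frame.
#' @return List with \code{group} (named 6-vector summing to 1) and
#'   \code{per_sample} (samples x 6 matrix of within-sample fractions;
#'   all-zero samples are dropped). With zero SNVs both elements are empty.
#' @export
substitutionFractions <- function(x, ...) {
  cat96 <- if (is(x, "TrinucleotideCatalog")) x else buildCatalog(x, ...)
  cls <- sub("^.\\[(.+)\\].$", "\\1", CONTEXTS_96)
  bycls <- t(apply(catalogCounts(cat96), 1L, function(r)
    tapply(r, factor(cls, levels = SUBSTITUTION_CLASSES), sum)))
  if (nrow(catalogCounts(cat96)) == 1L) {
    bycls <- matrix(bycls, nrow = 1L,
                    dimnames = list(catalogSamples(cat96), SUBSTITUTION_CLASSES))
  }
  colnames(bycls) <- SUBSTITUTION_CLASSES
  tot <- sum(bycls)
  if (tot == 0)
    return(list(group = stats::setNames(numeric(0), character(0)),
                per_sample = bycls[0, , drop = FALSE]))
  rs <- rowSums(bycls)
  per <- bycls[rs > 0, , drop = FALSE] / rs[rs > 0]
  list(group = colSums(bycls) / tot, per_sample = per)
}

#' Transition/transversion summary with a paired test
#'
#' Per-sample transition (C>T + T>C) versus transversion fractions compared
#' by a paired two-sided t test, the plotted unit being the per-sample
#' fraction. With fewer than two samples the summary is returned without a
#' p-value.
#'
#' @param per_sample Samples x 6 fraction matrix from
#'   [substitutionFractions()], or a [TrinucleotideCatalog-class].
#' @return List: \code{median_ti, median_tv, mean_ti, mean_tv, p_value}
#'   (fractions in [0,1]).
#' @export
titvSummary <- function(per_sample) {
  if (is(per_sample, "TrinucleotideCatalog"))
    per_sample <- substitutionFractions(per_sample)$per_sample
  ti <- rowSums(per_sample[, c("C>T", "T>C"), drop = FALSE])
  tv <- 1 - ti
  p <- NA_real_
  if (length(ti) >= 2L) {
    d <- ti - tv
    p <- if (stats::sd(d) == 0) {
      if (mean(d) == 0) 1 else 0
    } else stats::t.test(d)$p.value
  }
  list(median_ti = stats::median(ti), median_tv = stats::median(tv),
       mean_ti = mean(ti), mean_tv = mean(tv), p_value = p)
}

#' Transcriptional strand-bias fold excess
#'
#' Excess of coding-strand (pyrimidine-on-coding) over transcribed-strand
#' mutation counts for one substitution class, expressed as
#' \code{(n_forward - n_reverse) / n_reverse}: counts of 17 vs 5 give a
#' 2.4-fold excess.
#'
#' @param n_forward,n_reverse Non-negative counts.
#' @return Numeric fold excess; \code{Inf} with a warning when
#'   \code{n_reverse} is 0.
#' @export
strandFoldExcess <- function(n_forward, n_reverse) {
  stopifnot(n_forward >= 0, n_reverse >= 0)
  if (n_reverse == 0) {
    warning("n_reverse is 0; fold excess undefined (Inf)")
    return(Inf)
  }
  (n_forward - n_reverse) / n_reverse
}

#' Strand counts for one substitution class
#'
#' Sums the fwd/rev halves of a strand-split catalog over all contexts of
#' one class.
#'
#' @param catalog A stranded [TrinucleotideCatalog-class].
#' @param cls One of [SUBSTITUTION_CLASSES].
#' @return Named vector \code{c(forward=, reverse=)}.
#' @export
classStrandCounts <- function(catalog, cls) {
  stopifnot(cls %in% SUBSTITUTION_CLASSES)
  sc <- strandedCounts(catalog)
  if (nrow(sc) == 0L) stop("catalog was not built with stranded = TRUE")
  sel <- grepl(paste0("[", cls, "]"), colnames(sc), fixed = TRUE)
  fwd <- sum(sc[, sel & endsWith(colnames(sc), ":fwd"), drop = FALSE])
  rev <- sum(sc[, sel & endsWith(colnames(sc), ":rev"), drop = FALSE])
  c(forward = fwd, reverse = rev)
}

#' Compare a substitution class between two groups of cases
#'
#' Welch two-sample t test on per-case class fractions, plus the fraction of
#' cases in each group carrying at least one variant of the class.
#'
#' @param frac_a,frac_b Numeric vectors of per-case fractions (each length
#'   >= 2).
#' @return List: \code{mean_a, mean_b, median_a, median_b, welch_p,
#'   case_fraction_a, case_fraction_b}.
#' @export
compareClassBetweenGroups <- function(frac_a, frac_b) {
  stopifnot(length(frac_a) >= 2L, length(frac_b) >= 2L)
  wt <- welchTTest(frac_a, frac_b)
  list(mean_a = mean(frac_a), mean_b = mean(frac_b),
       median_a = stats::median(frac_a), median_b = stats::median(frac_b),
       welch_p = wt$p_two_sided,
       case_fraction_a = mean(frac_a > 0), case_fraction_b = mean(frac_b > 0))
}

#' Export a catalog in 96-row matrix layout
#'
#' Contexts as rows, samples as columns (SigProfiler-compatible).
#'
#' @param catalog A [TrinucleotideCatalog-class].
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  m <- t(catalogCounts(catalog))
  df <- data.frame(context = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a catalog written by [writeCatalog()]
#'
#' @param path TSV path, 96 context rows x sample columns.
#' @return A [TrinucleotideCatalog-class] (unstranded).
#' @export
readCatalog <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (nrow(m) != 96L) stop("catalog file must have 96 context rows")
  m <- t(m[CONTEXTS_96, , drop = FALSE])
  storage.mode(m) <- "integer"
  new("TrinucleotideCatalog", counts = m,
      strandedCounts = matrix(0L, 0L, 192L, dimnames = list(NULL, CONTEXTS_192)))
}
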