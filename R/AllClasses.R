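#' @import methods
NULL

## ---------------------------------------------------------------------------
## CHCohort: patients + variants
## ---------------------------------------------------------------------------

#' Cohort of patients with paired-compartment variant calls
#'
#' Container for a clinical table (one row per patient) and a variant table
#' (one row per called alteration per compartment). Variants must reference
#' patients present in the clinical table.
#'
#' @slot patients data.frame with columns \code{patient_id}, \code{diagnosis},
#'   \code{age_at_dx}, \code{smoking}, \code{flow_pct}, \code{tcrg},
#'   \code{morphology_pct}, \code{chn_event}, \code{followup_months}.
#' @slot variants data.frame in the layout produced by [readVariantTable()].
#' @export
setClass("CHCohort", slots = c(patients = "data.frame", variants = "data.frame"))

setValidity("CHCohort", function(object) {
  p <- object@patients; v <- object@variants
  msgs <- character()
  if (!"patient_id" %in% names(p)) msgs <- c(msgs, "patients lacks patient_id")
  if (nrow(v) > 0) {
    if (!"patient_id" %in% names(v)) msgs <- c(msgs, "variants lacks patient_id")
    else if (!all(v$patient_id %in% p$patient_id))
      msgs <- c(msgs, "variants reference unknown patient_id(s)")
    if ("vaf" %in% names(v) && any(v$vaf < 0 | v$vaf > 1, na.rm = TRUE))
      msgs <- c(msgs, "vaf outside [0,1]")
    if ("compartment" %in% names(v) && !all(v$compartment %in% c("LN", "BMPB")))
      msgs <- c(msgs, "compartment must be LN or BMPB")
  }
  if (anyDuplicated(p$patient_id)) msgs <- c(msgs, "duplicated patient_id in patients")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CHCohort
#'
#' @param patients Clinical data.frame (see [readClinicalTable()]).
#' @param variants Variant data.frame (see [readVariantTable()]).
#' @return A [CHCohort-class] object.
#' @export
CHCohort <- function(patients, variants) {
  new("CHCohort", patients = as.data.frame(patients),
      variants = as.data.frame(variants))
}

#' @describeIn CHCohort-class clinical table accessor
#' @param x A \code{CHCohort}.
#' @export
cohortPatients <- function(x) x@patients

#' @describeIn CHCohort-class variant table accessor
#' @export
cohortVariants <- function(x) x@variants

setMethod("show", "CHCohort", function(object) {
  cat("CHCohort:", nrow(object@patients), "patients,",
      nrow(object@variants), "variants\n")
  if (nrow(object@variants)) {
    tab <- table(object@variants$compartment)
    cat("  compartments:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

## ---------------------------------------------------------------------------
## TumorBurdenEstimate
## ---------------------------------------------------------------------------

#' Tumor-burden estimate for a bone-marrow/blood sample
#'
#' Estimated fraction of neoplastic T-cells in a BM/PB specimen, together
#' with the evidence tier used (flow cytometry, TCRG clonality, or the VAF
#' of a lymphoma-marker variant) and an interval.
#'
#' @slot patient_id character.
#' @slot tb numeric fraction in [0,1].
#' @slot method one of \code{"flow"}, \code{"tcrg"}, \code{"marker_vaf"},
#'   \code{"none"}.
#' @slot tb_low,tb_high numeric interval bounds, \code{tb_low <= tb <= tb_high}.
#' @export
setClass("TumorBurdenEstimate",
         slots = c(patient_id = "character", tb = "numeric", method = "character",
                   tb_low = "numeric", tb_high = "numeric"))

setValidity("TumorBurdenEstimate", function(object) {
  msgs <- character()
  if (!object@method %in% c("flow", "tcrg", "morphology", "marker_vaf", "none"))
    msgs <- c(msgs, "unknown method")
  if (object@tb < 0 || object@tb > 1) msgs <- c(msgs, "tb outside [0,1]")
  if (!(object@tb_low <= object@tb && object@tb <= object@tb_high))
    msgs <- c(msgs, "interval must satisfy tb_low <= tb <= tb_high")
  if (object@method == "none" && object@tb != 0)
    msgs <- c(msgs, "method 'none' implies tb = 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TumorBurdenEstimate", function(object) {
  cat(sprintf("TumorBurdenEstimate[%s]: tb=%.4f (%s; [%.4f, %.4f])\n",
              object@patient_id, object@tb, object@method,
              object@tb_low, object@tb_high))
})

## ---------------------------------------------------------------------------
## TrinucleotideCatalog
## ---------------------------------------------------------------------------

#' Per-sample 96-context SNV catalog
#'
#' Counts of single-nucleotide variants per sample in the 96 pyrimidine
#' trinucleotide contexts ([CONTEXTS_96]); optionally also split by
#' transcriptional strand into 192 bins ([CONTEXTS_192]).
#'
#' @slot counts integer matrix, samples x 96.
#' @slot strandedCounts samples x 192 matrix, or a 0-row matrix when the
#'   catalog was built unstranded. Strand-unknown SNVs contribute to
#'   \code{counts} only, so the two fwd/rev halves sum to at most the
#'   unstranded bin.
#' @export
setClass("TrinucleotideCatalog",
         slots = c(counts = "matrix", strandedCounts = "matrix"))

setValidity("TrinucleotideCatalog", function(object) {
  msgs <- character()
  if (ncol(object@counts) != 96L) msgs <- c(msgs, "counts must have 96 columns")
  if (!identical(colnames(object@counts), CONTEXTS_96))
    msgs <- c(msgs, "counts columns must be CONTEXTS_96 in canonical order")
  if (any(object@counts < 0)) msgs <- c(msgs, "negative counts")
  if (nrow(object@strandedCounts) > 0) {
    if (ncol(object@strandedCounts) != 192L ||
        !identical(colnames(object@strandedCounts), CONTEXTS_192))
      msgs <- c(msgs, "strandedCounts columns must be CONTEXTS_192")
    fwd <- object@strandedCounts[, seq(1L, 192L, by = 2L), drop = FALSE]
    rev <- object@strandedCounts[, seq(2L, 192L, by = 2L), drop = FALSE]
    if (any(fwd + rev > object@counts + 1e-9))
      msgs <- c(msgs, "stranded halves exceed unstranded bins")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn TrinucleotideCatalog-class samples x 96 count matrix
#' @param x A \code{TrinucleotideCatalog}.
#' @export
catalogCounts <- function(x) x@counts

#' @describeIn TrinucleotideCatalog-class samples x 192 strand-split counts
#'   (0-row matrix if unstranded)
#' @export
strandedCounts <- function(x) x@strandedCounts

#' @describeIn TrinucleotideCatalog-class sample identifiers
#' @export
catalogSamples <- function(x) rownames(x@counts)

setMethod("show", "TrinucleotideCatalog", function(object) {
  cat("TrinucleotideCatalog:", nrow(object@counts), "samples,",
      sum(object@counts), "SNVs",
      if (nrow(object@strandedCounts)) "(strand-split)" else "", "\n")
})

## ---------------------------------------------------------------------------
## SignatureSet / DeNovoSignatureSet
## ---------------------------------------------------------------------------

#' Set of 96-context mutational signature profiles
#'
#' Non-negative profiles over the 96 trinucleotide contexts, one row per
#' signature, each row summing to 1.
#'
#' @slot profiles numeric matrix, signatures x 96, rows sum to 1.
#' @export
setClass("SignatureSet", slots = c(profiles = "matrix"))

setValidity("SignatureSet", function(object) {
  p <- object@profiles
  msgs <- character()
  if (ncol(p) != 96L) msgs <- c(msgs, "profiles must have 96 columns")
  if (!identical(colnames(p), CONTEXTS_96))
    msgs <- c(msgs, "profile columns must be CONTEXTS_96 in canonical order")
  if (any(p < 0)) msgs <- c(msgs, "negative profile entries")
  if (nrow(p) > 0 && any(abs(rowSums(p) - 1) > 1e-6))
    msgs <- c(msgs, "profile rows must sum to 1 (+/- 1e-6)")
  if (is.null(rownames(p)) && nrow(p) > 0) msgs <- c(msgs, "profiles need rownames")
  if (length(msgs)) msgs else TRUE
})

#' De novo signatures from bootstrapped NMF
#'
#' @slot stability per-signature mean silhouette width in [-1, 1]
#'   (\code{NA} when k = 1, where silhouettes are undefined).
#' @slot k number of signatures extracted.
#' @slot seed RNG seed used.
#' @slot nBootstrap number of bootstrap resamples pooled.
#' @slot converged logical, whether all NMF runs met the tolerance.
#' @export
setClass("DeNovoSignatureSet", contains = "SignatureSet",
         slots = c(stability = "numeric", k = "integer", seed = "integer",
                   nBootstrap = "integer", converged = "logical"))

#' Construct a SignatureSet
#'
#' Rows are renormalized to sum to 1; columns must be the 96 canonical
#' contexts (any order; they are re-ordered).
#'
#' @param profiles signatures x 96 non-negative matrix with context colnames
#'   and signature rownames.
#' @return A [SignatureSet-class].
#' @export
SignatureSet <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (is.null(colnames(profiles)) && ncol(profiles) == 96L)
    colnames(profiles) <- CONTEXTS_96
  if (!setequal(colnames(profiles), CONTEXTS_96))
    stop("profiles must cover exactly the 96 canonical contexts")
  profiles <- profiles[, CONTEXTS_96, drop = FALSE]
  if (any(profiles < 0)) stop("negative profile entries")
  rs <- rowSums(profiles)
  if (any(rs <= 0)) stop("zero-sum profile row")
  new("SignatureSet", profiles = profiles / rs)
}

#' @describeIn SignatureSet-class profile matrix accessor
#' @param x A \code{SignatureSet}.
#' @export
signatureProfiles <- function(x) x@profiles

#' @describeIn SignatureSet-class signature names
#' @export
signatureNames <- function(x) rownames(x@profiles)

#' @describeIn DeNovoSignatureSet-class per-signature mean silhouette widths
#' @param x A \code{DeNovoSignatureSet}.
#' @export
signatureStability <- function(x) x@stability

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet:", nrow(object@profiles), "signatures x 96 contexts\n")
})

setMethod("show", "DeNovoSignatureSet", function(object) {
  cat("DeNovoSignatureSet: k =", object@k,
      "| bootstraps =", object@nBootstrap,
      "| stability =", paste(round(object@stability, 3), collapse = ", "), "\n")
})
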