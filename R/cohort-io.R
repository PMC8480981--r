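## Readers/writers for variant tables, clinical tables and reference
## signature matrices, plus the post-alignment variant filter.

.VARIANT_COLUMNS <- c("patient_id", "compartment", "gene", "chrom", "pos",
                      "ref", "alt", "context3", "coding_strand_ref", "vclass",
                      "tier", "vaf", "popfreq", "strand_balance", "rescued")

.MANDATORY_VARIANT_COLUMNS <- c("patient_id", "compartment", "gene", "chrom",
                                "pos", "ref", "alt", "vaf")

.VCLASS_LEVELS <- c("missense", "nonsense", "frameshift_ins", "frameshift_del",
                    "inframe_ins", "inframe_del", "splice", "other")

## coerce and validate a raw variant data.frame to the canonical layout
normalizeVariantTable <- function(df) {
  missing_cols <- setdiff(.MANDATORY_VARIANT_COLUMNS, names(df))
  if (length(missing_cols))
    stop("variant table missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in setdiff(.VARIANT_COLUMNS, names(df)))
    df[[col]] <- switch(col,
                        context3 = NA_character_,
                        coding_strand_ref = "unknown",
                        vclass = "other",
                        tier = NA_integer_,
                        popfreq = NA_real_,
                        strand_balance = NA_real_,
                        rescued = FALSE)

  df$pos <- suppressWarnings(as.numeric(df$pos))
  df$vaf <- suppressWarnings(as.numeric(df$vaf))
  if (anyNA(df$pos) || anyNA(df$vaf))
    stop("unparseable pos or vaf value(s) in variant table")
  if (any(df$pos < 1)) stop("pos must be >= 1 (1-based coordinates)")
  if (any(df$vaf < 0 | df$vaf > 1))
    stop("vaf outside [0,1]")
  if (!all(df$compartment %in% c("LN", "BMPB")))
    stop("compartment must be 'LN' or 'BMPB'")

  unknown_vclass <- !(df$vclass %in% .VCLASS_LEVELS) & !is.na(df$vclass)
  if (any(unknown_vclass)) {
    warning("unknown vclass value(s) mapped to 'other': ",
            paste(unique(df$vclass[unknown_vclass]), collapse = ", "))
    df$vclass[unknown_vclass] <- "other"
  }
  df$vclass[is.na(df$vclass)] <- "other"
  df$coding_strand_ref[is.na(df$coding_strand_ref)] <- "unknown"
  if (!all(df$coding_strand_ref %in% c("same", "opposite", "unknown")))
    stop("coding_strand_ref must be same/opposite/unknown")
  df$tier <- suppressWarnings(as.integer(df$tier))
  df$rescued <- as.logical(df$rescued)
  df$rescued[is.na(df$rescued)] <- FALSE

  is_snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    df$ref %in% .BASES & df$alt %in% .BASES
  has_ctx <- is_snv & !is.na(df$context3)
  if (any(has_ctx & substr(df$context3, 2L, 2L) != df$ref))
    stop("context3 middle base does not match ref for SNV row(s)")

  extra <- setdiff(names(df), .VARIANT_COLUMNS)
  df[, c(.VARIANT_COLUMNS, extra), drop = FALSE]
}

#' Read a tab-separated variant table
#'
#' One row per called variant per compartment. Mandatory columns:
#' \code{patient_id, compartment, gene, chrom, pos, ref, alt, vaf};
#' recognized optional columns: \code{context3} (ref-strand trinucleotide
#' centered on the mutated base), \code{coding_strand_ref}
#' (same/opposite/unknown: whether the reference strand is the coding strand
#' at the site), \code{vclass}, \code{tier}, \code{popfreq},
#' \code{strand_balance}, \code{rescued} and any extra annotation columns
#' (e.g. \code{func_pred}), which are carried through untouched.
#'
#' @param path Path to a TSV file with a header row.
#' @return data.frame in canonical column order.
#' @export
readVariantTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  normalizeVariantTable(df)
}

#' Write a variant table as TSV
#'
#' @param variants Variant data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeVariantTable <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a clinical table (CSV)
#'
#' Expected columns: \code{patient_id, diagnosis, age_at_dx, smoking,
#' flow_pct, tcrg, morphology_pct, chn_event, followup_months}. Missing
#' optional columns are filled with \code{NA}.
#'
#' @param path Path to a CSV file.
#' @return data.frame, one row per patient.
#' @export
readClinicalTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df))
    stop("clinical table missing mandatory column: patient_id")
  for (col in c("diagnosis", "smoking", "tcrg"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  for (col in c("age_at_dx", "flow_pct", "morphology_pct", "followup_months"))
    if (!col %in% names(df)) df[[col]] <- NA_real_
  if (!"chn_event" %in% names(df)) df$chn_event <- NA_integer_
  if (any(df$followup_months < 0, na.rm = TRUE))
    stop("followup_months must be >= 0")
  if (!all(df$chn_event %in% c(0L, 1L, NA)))
    stop("chn_event must be 0/1")
  df
}

#' Post-alignment variant filter
#'
#' Applies the targeted-sequencing post-alignment cutoffs: minimum VAF 5%,
#' maximum population frequency 0.01%, and minimum strand-balance ratio 0.2
#' (the \dQuote{1:5} minor/major strand read ratio read as a lower cutoff).
#' If a \code{func_pred} column (count of damaging in-silico predictions) is
#' present, rows must additionally exceed \code{func_pred_min}. \code{NA}
#' popfreq/strand_balance pass their respective filters; rows flagged
#' \code{rescued} (re-genotyped at a known site in the other compartment)
#' bypass the VAF cutoff.
#'
#' The filter is idempotent and preserves row order.
#'
#' @param variants Variant data.frame.
#' @param vaf_min Minimum VAF (default 0.05).
#' @param popfreq_max Maximum population frequency (default 1e-4).
#' @param strand_balance_min Minimum strand balance ratio (default 0.2).
#' @param func_pred_min Exclusive lower cutoff on \code{func_pred}, applied
#'   only when that column exists (default 2).
#' @return Filtered variant data.frame.
#' @export
applyPostFilters <- function(variants, vaf_min = 0.05, popfreq_max = 1e-4,
                             strand_balance_min = 0.2, func_pred_min = 2) {
  stopifnot(vaf_min >= 0, vaf_min <= 1, popfreq_max >= 0, popfreq_max <= 1)
  if (nrow(variants) == 0L) return(variants)
  rescued <- if ("rescued" %in% names(variants)) {
    r <- as.logical(variants$rescued); r[is.na(r)] <- FALSE; r
  } else rep(FALSE, nrow(variants))
  keep <- (variants$vaf >= vaf_min | rescued)
  if ("popfreq" %in% names(variants))
    keep <- keep & (is.na(variants$popfreq) | variants$popfreq <= popfreq_max)
  if ("strand_balance" %in% names(variants))
    keep <- keep & (is.na(variants$strand_balance) |
                      variants$strand_balance >= strand_balance_min)
  if ("func_pred" %in% names(variants))
    keep <- keep & (is.na(variants$func_pred) |
                      variants$func_pred > func_pred_min)
  variants[keep, , drop = FALSE]
}

#' Read a reference signature matrix
#'
#' Reads a COSMIC-v2-style TSV: either 96 context rows x signature columns
#' (with context labels in the first column) or the transposed layout
#' (signature rows x 96 context columns); the orientation is auto-detected
#' from which dimension carries the 96 context labels. Profiles are
#' renormalized to sum to 1 and contexts re-ordered canonically.
#'
#' @param path Path to the TSV.
#' @return A [SignatureSet-class].
#' @export
readReferenceSignatures <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  first <- df[[1L]]
  looks_ctx <- function(x) mean(grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", x)) > 0.9
  if (looks_ctx(as.character(first))) {
    if (nrow(df) != 96L)
      stop("reference signature file must carry exactly 96 contexts (found ",
           nrow(df), ")")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(first)
    m <- t(m)                               # -> signatures x 96
  } else if (looks_ctx(names(df)[-1L])) {
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(first)
    if (ncol(m) != 96L)
      stop("reference signature file must carry exactly 96 contexts (found ",
           ncol(m), ")")
  } else {
    stop("cannot locate 96 trinucleotide context labels in file")
  }
  storage.mode(m) <- "double"
  if (any(is.na(m))) stop("non-numeric entries in signature matrix")
  if (any(m < 0)) stop("negative entries in signature matrix")
  SignatureSet(m)
}

#' Write a signature set in 96-row matrix layout
#'
#' Writes the transposed (contexts x signatures) layout with a leading
#' context column, round-trippable by [readReferenceSignatures()].
#'
#' @param sigset A [SignatureSet-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSignatureSet <- function(sigset, path) {
  m <- t(signatureProfiles(sigset))
  df <- data.frame(context = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
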