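## Substitution classes and the canonical 96-context ordering shared by the
## catalog, signature and simulation code.

#' Six pyrimidine substitution classes
#'
#' Single-base substitutions collapsed onto the pyrimidine of the Watson-Crick
#' pair, in the conventional order used throughout the package.
#'
#' @format Character vector of length 6: \code{C>A, C>G, C>T, T>A, T>C, T>G}.
#' @export
SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Canonical 96 trinucleotide context labels
#'
#' All \code{5'[class]3'} combinations, sorted lexicographically
#' (\code{A[C>A]A} first, \code{T[T>G]T} last). This is the fixed column
#' order of every catalog and signature matrix in the package.
#'
#' @format Character vector of length 96.
#' @export
CONTEXTS_96 <- local({
  x <- as.vector(outer(
    .BASES,
    as.vector(outer(SUBSTITUTION_CLASSES, .BASES,
                    function(cls, b3) paste0("[", cls, "]", b3))),
    paste0))
  sort(x, method = "radix")
})

#' Labels for the strand-split 192-context catalog
#'
#' Each of the 96 contexts split by whether the mutated pyrimidine lies on
#' the coding (untranscribed) strand (\code{fwd}) or on the transcribed
#' strand (\code{rev}).
#'
#' @format Character vector of length 192.
#' @export
CONTEXTS_192 <- as.vector(rbind(paste0(CONTEXTS_96, ":fwd"),
                                paste0(CONTEXTS_96, ":rev")))

complementBase <- function(b) {
  out <- .COMPLEMENT[b]
  if (anyNA(out)) stop("invalid base(s): ", paste(b[is.na(out)], collapse = ", "))
  unname(out)
}

reverseComplement <- function(s) {
  vapply(strsplit(s, ""), function(ch)
    paste(rev(complementBase(ch)), collapse = ""), character(1))
}

#' Classify a single-base substitution
#'
#' Collapses a ref/alt base pair onto the pyrimidine strand: purine-reference
#' substitutions are complemented, so e.g. G>T becomes C>A.
#'
#' @param ref,alt Single reference/alternate bases (vectorized).
#' @return Character vector of classes from [SUBSTITUTION_CLASSES].
#' @examples
#' classifySubstitution("C", "T")  # "C>T"
#' classifySubstitution("G", "T")  # "C>A"
#' @export
classifySubstitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% .BASES & alt %in% .BASES & nchar(ref) == 1L & nchar(alt) == 1L
  if (!all(ok)) stop("classifySubstitution: not a single-nucleotide substitution")
  if (any(ref == alt)) stop("classifySubstitution: ref == alt")
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, complementBase(ref), ref)
  a <- ifelse(pur, complementBase(alt), alt)
  cls <- paste0(r, ">", a)
  stopifnot(all(cls %in% SUBSTITUTION_CLASSES))
  cls
}

#' Is a substitution class a transition?
#'
#' @param cls Classes from [SUBSTITUTION_CLASSES].
#' @return Logical; \code{TRUE} for C>T and T>C only.
#' @export
isTransition <- function(cls) {
  if (!all(cls %in% SUBSTITUTION_CLASSES))
    stop("unknown substitution class: ", paste(setdiff(cls, SUBSTITUTION_CLASSES), collapse = ", "))
  cls %in% c("C>T", "T>C")
}

## Map (context3 on the reference strand, ref, alt) to a 96-bin label.
## Purine-reference variants are reverse-complemented before binning.
contextBin <- function(context3, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt); context3 <- toupper(context3)
  if (any(nchar(context3) != 3L))
    stop("context3 must be a 3-base string")
  if (any(substr(context3, 2L, 2L) != ref))
    stop("context3 middle base does not match ref allele")
  pur <- ref %in% c("A", "G")
  ctx <- ifelse(pur, reverseComplement(context3), context3)
  cls <- classifySubstitution(ref, alt)
  paste0(substr(ctx, 1L, 1L), "[", cls, "]", substr(ctx, 3L, 3L))
}

## half-up decimal rounding (display convention for percentages)
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
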