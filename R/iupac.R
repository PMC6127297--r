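#' @keywords internal
#' @name iupac-tables
#' @noRd
NULL

# Bit encoding of IUPAC nucleotide codes: A=1, C=2, G=4, T=8.
# Two symbols are compatible iff their expansion sets intersect,
# i.e. iff the bitwise AND of their masks is non-zero.
.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L,  Y = 10L, S = 6L,  W = 9L,
  K = 12L, M = 3L,  B = 14L, D = 13L,
  H = 11L, V = 7L,  N = 15L
)

# Inverse map: bitmask -> canonical code (U never produced).
.BITS_TO_CODE <- character(15L)
.BITS_TO_CODE[c(1L, 2L, 4L, 8L)] <- c("A", "C", "G", "T")
.BITS_TO_CODE[c(5L, 10L, 6L, 9L, 12L, 3L)] <- c("R", "Y", "S", "W", "K", "M")
.BITS_TO_CODE[c(14L, 13L, 11L, 7L)] <- c("B", "D", "H", "V")
.BITS_TO_CODE[15L] <- "N"

.IUPAC_FROM <- "ACGTURYSWKMBDHVN"
.IUPAC_COMP <- "TGCAAYRSWMKVHDBN"

# Fraction of each code's expansion that is G or C (used for Tm).
.IUPAC_GC_WEIGHT <- c(
  A = 0, C = 1, G = 1, T = 0, U = 0,
  R = 0.5, Y = 0.5, S = 1, W = 0,
  K = 0.5, M = 0.5, B = 2 / 3, D = 1 / 3,
  H = 1 / 3, V = 2 / 3, N = 0.5
)

.seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# Bitmasks for a character vector of symbols; stops with the offending
# position when a symbol is not an IUPAC code.
.iupac_bits <- function(chars, context = "sequence") {
  bits <- .IUPAC_BITS[chars]
  if (anyNA(bits)) {
    bad <- which(is.na(bits))[1L]
    stop(sprintf("non-IUPAC character '%s' at position %d in %s",
                 chars[bad], bad, context), call. = FALSE)
  }
  unname(bits)
}

#' Normalize a nucleotide string
#'
#' Uppercases and converts U to T. Errors (naming the position) if any
#' remaining character is not an IUPAC nucleotide code.
#'
#' @param seq Character scalar.
#' @param context Label used in error messages (e.g. a record id).
#' @return Normalized character scalar over the IUPAC DNA alphabet.
#' @export
normalize_seq <- function(seq, context = "sequence") {
  out <- chartr("u", "T", chartr("U", "T", toupper(seq)))
  .iupac_bits(.seq_chars(out), context)
  out
}

#' Reverse complement of an IUPAC string
#'
#' Standard IUPAC complementation (R<->Y, K<->M, B<->V, D<->H, S, W, N fixed)
#' followed by reversal. Accepts a character vector; U complements to A.
#'
#' @param seq Character vector of IUPAC strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGT") # "ACGT"
#' revcomp("RAA")  # "TTY"
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    chars <- .seq_chars(toupper(s))
    .iupac_bits(chars, "sequence")
    comp <- chartr(.IUPAC_FROM, .IUPAC_COMP, paste(chars, collapse = ""))
    paste(rev(.seq_chars(comp)), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Are two IUPAC symbols compatible?
#'
#' TRUE iff the expansion sets of `a` and `b` intersect (so `N` is
#' compatible with everything and e.g. R/Y are incompatible). Vectorized
#' and symmetric.
#'
#' @param a,b IUPAC symbols (character vectors, recycled).
#' @return Logical vector.
#' @export
iupac_compatible <- function(a, b) {
  bitwAnd(.iupac_bits(toupper(a), "first argument"),
          .iupac_bits(toupper(b), "second argument")) > 0L
}

#' Degenerate-aware mismatch count between equal-length strings
#'
#' Counts positions where the two symbols' IUPAC expansion sets do not
#' intersect. Symmetric in its arguments.
#'
#' @param primer,window IUPAC strings of equal length.
#' @return Integer mismatch count.
#' @examples
#' count_mismatches("MTAYMYTACC", "CTACCTTACC") # 0
#' @export
count_mismatches <- function(primer, window) {
  a <- .seq_chars(toupper(primer))
  b <- .seq_chars(toupper(window))
  if (length(a) != length(b)) {
    stop(sprintf("length mismatch: %d vs %d", length(a), length(b)),
         call. = FALSE)
  }
  sum(!iupac_compatible(a, b))
}

# Minimal IUPAC code covering a set of concrete bases.
.cover_code <- function(bases) {
  .BITS_TO_CODE[Reduce(bitwOr, .IUPAC_BITS[bases], accumulate = FALSE)]
}

# Deterministic concrete realization of a degenerate string: every
# ambiguity code is resolved to the alphabetically first base it covers.
.resolve_iupac <- function(seq) {
  chars <- .seq_chars(toupper(seq))
  bits <- .iupac_bits(chars, "sequence")
  base <- character(length(bits))
  base[bitwAnd(bits, 8L) > 0L] <- "T"
  base[bitwAnd(bits, 4L) > 0L] <- "G"
  base[bitwAnd(bits, 2L) > 0L] <- "C"
  base[bitwAnd(bits, 1L) > 0L] <- "A"
  paste(base, collapse = "")
}
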