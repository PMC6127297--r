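#' Construct a primer set
#'
#' A primer pair for one marker region. Both primers are written 5'->3';
#' the reverse primer anneals to the forward strand as its reverse
#' complement. An optional blocking primer (also 5'->3', reverse-primer
#' orientation) and expected amplicon length can be attached.
#'
#' @param name Marker/primer-set name (e.g. "18SV1V2").
#' @param forward,reverse IUPAC strings, length >= 10 each.
#' @param blocker Optional blocking-primer IUPAC string.
#' @param expected_amplicon_len Optional integer hint (bp).
#' @return An object of class `primer_set`.
#' @export
primer_set <- function(name, forward, reverse, blocker = NULL,
                       expected_amplicon_len = NULL) {
  forward <- normalize_seq(forward, sprintf("forward primer of %s", name))
  reverse <- normalize_seq(reverse, sprintf("reverse primer of %s", name))
  if (nchar(forward) < 10L || nchar(reverse) < 10L) {
    stop("primers must be at least 10 nt long", call. = FALSE)
  }
  if (!is.null(blocker)) {
    blocker <- normalize_seq(blocker, sprintf("blocking primer of %s", name))
  }
  structure(
    list(name = name, forward = forward, reverse = reverse,
         blocker = blocker,
         expected_amplicon_len = expected_amplicon_len),
    class = "primer_set"
  )
}

#' @export
print.primer_set <- function(x, ...) {
  cat(sprintf("Primer set '%s'\n", x$name))
  cat(sprintf("  forward (5'->3'): %s\n", x$forward))
  cat(sprintf("  reverse (5'->3'): %s\n", x$reverse))
  if (!is.null(x$blocker)) {
    cat(sprintf("  blocking primer : %s\n", x$blocker))
  }
  if (!is.null(x$expected_amplicon_len)) {
    cat(sprintf("  expected amplicon: ~%d bp\n", x$expected_amplicon_len))
  }
  invisible(x)
}

#' Published Scleractinia-blocking 18S primer sets
#'
#' The two 18S rRNA primer sets (V1V2 and V4 variable loops) used for
#' coral-associated protist metabarcoding, together with the published
#' Scleractinia blocking primers designed against them. The blocking
#' primers are synthesized with a 3' Spacer C3 CPG so that they anneal but
#' cannot be extended; that modification is metadata, not sequence.
#'
#' @return Named list of two `primer_set` objects ("18SV1V2", "18SV4").
#' @examples
#' sets <- scleractinia_primer_sets()
#' primer_blocker_overlap(sets[["18SV1V2"]]$reverse, sets[["18SV1V2"]]$blocker)
#' @export
scleractinia_primer_sets <- function() {
  list(
    "18SV1V2" = primer_set(
      name = "18SV1V2",
      forward = "ACCTGGTTGATCCTGCCA",
      reverse = "GTARKCCWMTAYMYTACC",
      blocker = "CTACCTTACCATCGACAGTTGATAG",
      expected_amplicon_len = 340L
    ),
    "18SV4" = primer_set(
      name = "18SV4",
      forward = "CCAGCASCYGCGGTAATTCC",
      reverse = "ACTTTCGTTCTTGATYRA",
      blocker = "TCTTGATTAATGAAAACATTCTTGGC",
      expected_amplicon_len = 430L
    )
  )
}

#' Degenerate suffix-prefix overlap between a reverse primer and a blocker
#'
#' Length of the longest suffix of `reverse` whose symbols are pairwise
#' IUPAC-compatible with the prefix of `blocker` of the same length. This
#' is the number of bases by which the blocking primer overlaps the
#' reverse primer's 3' end on the template.
#'
#' @param reverse Reverse primer (5'->3', IUPAC).
#' @param blocker Blocking primer (5'->3', IUPAC).
#' @return Integer overlap length (0 if no compatible overlap).
#' @export
primer_blocker_overlap <- function(reverse, blocker) {
  r <- .seq_chars(normalize_seq(reverse, "reverse primer"))
  b <- .seq_chars(normalize_seq(blocker, "blocking primer"))
  for (k in seq(min(length(r), length(b)), 1L)) {
    if (all(iupac_compatible(r[seq(length(r) - k + 1L, length(r))],
                             b[seq_len(k)]))) {
      return(k)
    }
  }
  0L
}

#' Read a primer set from a JSON or YAML file
#'
#' The file must contain fields `name`, `forward`, `reverse` and may
#' contain `blocker` and `expected_amplicon_len`.
#'
#' @param path File path; format chosen by extension (.json vs .yml/.yaml).
#' @return A `primer_set`.
#' @export
read_primer_set <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (f in c("name", "forward", "reverse")) {
    if (is.null(x[[f]])) stop("primer set file missing field '", f, "'",
                              call. = FALSE)
  }
  primer_set(x$name, x$forward, x$reverse, blocker = x$blocker,
             expected_amplicon_len = x$expected_amplicon_len)
}
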