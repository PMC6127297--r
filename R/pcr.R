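# Degenerate in silico PCR: primer-site scanning and amplicon extraction.

# All start positions (1-based) where `primer` matches `chars` with at
# most `max_mismatch` degenerate-aware mismatches, with the mismatch count
# at each start. O(primer length * sequence length), vectorized per
# primer position.
.scan_sites <- function(chars, primer, max_mismatch) {
  pc <- .seq_chars(primer)
  L <- length(pc)
  n <- length(chars)
  if (n < L) return(data.frame(start = integer(0L), mm = integer(0L)))
  sbits <- .iupac_bits(chars, "sequence")
  pbits <- .iupac_bits(pc, "primer")
  starts <- seq_len(n - L + 1L)
  mm <- integer(length(starts))
  for (i in seq_len(L)) {
    mm <- mm + (bitwAnd(pbits[i], sbits[starts + i - 1L]) == 0L)
  }
  keep <- mm <= max_mismatch
  data.frame(start = starts[keep], mm = mm[keep])
}

.no_amplicon <- function(id, which_primer) {
  stop(structure(
    class = c("no_amplicon", "error", "condition"),
    list(message = sprintf("no amplicon for record %s: %s primer site not found",
                           id, which_primer),
         call = NULL, record_id = id, primer = which_primer)))
}

#' Extract the amplicon a primer set defines on a record
#'
#' Scans the forward strand for a forward-primer site within
#' `max_mismatch` degenerate-aware mismatches and, downstream of it, for
#' the site of the reverse complement of the reverse primer. The hit uses
#' the FIRST forward site and the LAST compatible reverse site after it
#' (favoring the full-length amplicon); the amplicon includes both
#' primer-binding sites. Coordinates are 1-based and inclusive on the
#' reported strand. With `both_strands = TRUE` the reverse complement of
#' the record is scanned when the forward strand yields no amplicon, and
#' the hit is reported on that normalized orientation (`strand = "-"`).
#'
#' An `N` in the record matches anything (ambiguity-intersection
#' semantics); hits whose windows contain more than 20% N are flagged via
#' the `n_flag` field.
#'
#' @param rec A list with elements `id` and `seq` (normalized), or a
#'   single-record [ref_db].
#' @param primers A [primer_set].
#' @param max_mismatch Per-primer mismatch budget (default 0).
#' @param both_strands Scan the reverse strand as a fallback (default
#'   FALSE).
#' @return An object of class `amplicon_hit`: list with `record_id`,
#'   `start`, `end`, `amplicon`, `fwd_mismatches`, `rev_mismatches`,
#'   `rev_site_start`, `strand`, `n_flag`.
#' @export
extract_amplicon <- function(rec, primers, max_mismatch = 0L,
                             both_strands = FALSE) {
  stopifnot(inherits(primers, "primer_set"))
  if (inherits(rec, "ref_db")) {
    stopifnot(length(rec) == 1L)
    rec <- list(id = rec$ids[1L], seq = rec$seqs[1L])
  }
  .try_strand <- function(seq, strand) {
    chars <- .seq_chars(seq)
    flen <- nchar(primers$forward)
    rsite <- revcomp(primers$reverse)
    rlen <- nchar(rsite)
    fhits <- .scan_sites(chars, primers$forward, max_mismatch)
    if (nrow(fhits) == 0L) return(list(fail = "forward"))
    fs <- fhits$start[1L]
    fmm <- fhits$mm[1L]
    rhits <- .scan_sites(chars, rsite, max_mismatch)
    rhits <- rhits[rhits$start >= fs + flen, , drop = FALSE]
    if (nrow(rhits) == 0L) return(list(fail = "reverse"))
    rs <- rhits$start[nrow(rhits)]
    rmm <- rhits$mm[nrow(rhits)]
    end <- rs + rlen - 1L
    amplicon <- substr(seq, fs, end)
    fwd_window <- substr(seq, fs, fs + flen - 1L)
    rev_window <- substr(seq, rs, end)
    n_frac <- mean(.seq_chars(paste0(fwd_window, rev_window)) == "N")
    structure(
      list(record_id = rec$id, start = fs, end = end, amplicon = amplicon,
           fwd_mismatches = fmm, rev_mismatches = rmm,
           rev_site_start = rs, strand = strand, n_flag = n_frac > 0.2),
      class = "amplicon_hit")
  }
  hit <- .try_strand(rec$seq, "+")
  if (!is.null(hit$fail) && both_strands) {
    hit2 <- .try_strand(revcomp(rec$seq), "-")
    if (is.null(hit2$fail)) return(hit2)
  }
  if (!is.null(hit$fail)) .no_amplicon(rec$id, hit$fail)
  hit
}

#' @export
print.amplicon_hit <- function(x, ...) {
  cat(sprintf("Amplicon hit for %s (%s strand): %d-%d (%d bp), %d+%d mismatches\n",
              x$record_id, x$strand, x$start, x$end, nchar(x$amplicon),
              x$fwd_mismatches, x$rev_mismatches))
  invisible(x)
}

#' Extract amplicons for every record of a database
#'
#' Applies [extract_amplicon] to each record, dropping records without an
#' amplicon (their count is reported in a message and as the `n_dropped`
#' attribute).
#'
#' @inheritParams filter_amplifiable
#' @return A data.frame with columns `record_id`, `start`, `end`,
#'   `length`, `fwd_mm`, `rev_mm`, `rev_site_start`, `strand`, `amplicon`.
#' @export
extract_amplicons <- function(db, primers, max_mismatch = 0L,
                              both_strands = FALSE) {
  stopifnot(inherits(db, "ref_db"))
  hits <- lapply(seq_along(db$ids), function(i) {
    tryCatch(
      extract_amplicon(list(id = db$ids[i], seq = db$seqs[i]), primers,
                       max_mismatch = max_mismatch,
                       both_strands = both_strands),
      no_amplicon = function(e) NULL)
  })
  ok <- !vapply(hits, is.null, logical(1L))
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message(sprintf("%d record(s) without amplicon dropped", n_dropped))
  }
  hits <- hits[ok]
  out <- data.frame(
    record_id = vapply(hits, `[[`, character(1L), "record_id"),
    start = vapply(hits, `[[`, integer(1L), "start"),
    end = vapply(hits, `[[`, integer(1L), "end"),
    length = vapply(hits, function(h) nchar(h$amplicon), integer(1L)),
    fwd_mm = vapply(hits, `[[`, integer(1L), "fwd_mismatches"),
    rev_mm = vapply(hits, `[[`, integer(1L), "rev_mismatches"),
    rev_site_start = vapply(hits, `[[`, integer(1L), "rev_site_start"),
    strand = vapply(hits, `[[`, character(1L), "strand"),
    amplicon = vapply(hits, `[[`, character(1L), "amplicon"),
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- n_dropped
  out
}
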