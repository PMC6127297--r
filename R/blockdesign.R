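# Blocking-primer design: anchored tail stacks, column entropy, melting
# temperature, candidate enumeration and ranking.

#' Oligonucleotide melting temperature
#'
#' Wallace rule `2(A+T) + 4(G+C)` for sequences of 13 nt or fewer, the
#' GC-content formula `64.9 + 41 (GC - 16.4) / N` for 14 nt and longer.
#' Degenerate symbols contribute the mean GC weight of their expansion
#' (R counts 0.5 toward GC, B counts 2/3, ...), so a primer and its
#' reverse complement have identical Tm.
#'
#' @param seq IUPAC string, length >= 10.
#' @return Melting temperature in degrees Celsius.
#' @examples
#' melting_temperature("AAAATTTTGGCC")       # 32
#' melting_temperature("ACCTGGTTGATCCTGCCA") # 50.32
#' @export
melting_temperature <- function(seq) {
  chars <- .seq_chars(toupper(seq))
  .iupac_bits(chars, "sequence")
  n <- length(chars)
  if (n < 10L) stop("melting_temperature requires length >= 10",
                    call. = FALSE)
  gc <- sum(.IUPAC_GC_WEIGHT[chars])
  if (n <= 13L) 2 * (n - gc) + 4 * gc else 64.9 + 41 * (gc - 16.4) / n
}

#' Anchored stack of amplicon 3'-tails
#'
#' Takes the final `tail_len` bases of each amplicon (forward strand),
#' right-aligned so that the last `nchar(reverse)` columns are the
#' reverse-primer binding site. No gaps are inserted: because every row is
#' anchored on the same primer site, the stack is equivalent to a gapless
#' multiple alignment for indel-free tails (an externally aligned FASTA can
#' be supplied instead via [tail_stack_from_rows] for exact replication of
#' an aligner-based workflow). Amplicons shorter than `tail_len` are
#' dropped with a message.
#'
#' @param amplicons Data.frame from [extract_amplicons] (needs columns
#'   `record_id`, `amplicon`), or a named character vector of amplicons.
#' @param tail_len Tail length in bases (default 40).
#' @param primerset_name Label stored on the stack.
#' @return An object of class `tail_stack`: list with `rows` (named
#'   character vector), `tail_len`, `primerset_name`, and `freqs`
#'   (4 x tail_len matrix of per-column A/C/G/T relative frequencies over
#'   unambiguous symbols; all-ambiguous columns are NA).
#' @export
extract_tail_stack <- function(amplicons, tail_len = 40L,
                               primerset_name = "") {
  if (is.data.frame(amplicons)) {
    amps <- amplicons$amplicon
    names(amps) <- amplicons$record_id
  } else {
    amps <- amplicons
  }
  if (length(amps) == 0L) stop("no amplicons supplied", call. = FALSE)
  if (is.null(names(amps))) names(amps) <- paste0("seq", seq_along(amps))
  lens <- nchar(amps)
  short <- lens < tail_len
  if (any(short)) {
    message(sprintf("%d amplicon(s) shorter than tail_len dropped",
                    sum(short)))
    amps <- amps[!short]
    lens <- lens[!short]
  }
  if (length(amps) == 0L) stop("all amplicons shorter than tail_len",
                               call. = FALSE)
  rows <- substr(amps, lens - tail_len + 1L, lens)
  tail_stack_from_rows(rows, primerset_name = primerset_name)
}

#' Build a tail stack from pre-extracted (or pre-aligned) rows
#'
#' @param rows Named character vector of equal-length sequences.
#' @param primerset_name Label stored on the stack.
#' @return A `tail_stack` (see [extract_tail_stack]).
#' @export
tail_stack_from_rows <- function(rows, primerset_name = "") {
  if (length(rows) == 0L) stop("no rows supplied", call. = FALSE)
  tail_len <- unique(nchar(rows))
  if (length(tail_len) != 1L) {
    stop("all stack rows must have the same length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  freqs <- apply(mat, 2L, function(col) {
    counts <- tabulate(match(col, bases), nbins = 4L)
    if (sum(counts) == 0L) rep(NA_real_, 4L) else counts / sum(counts)
  })
  rownames(freqs) <- bases
  structure(
    list(rows = rows, tail_len = as.integer(tail_len),
         primerset_name = primerset_name, freqs = freqs),
    class = "tail_stack")
}

#' @export
print.tail_stack <- function(x, ...) {
  cat(sprintf("Tail stack%s: %d rows x %d columns\n",
              if (nzchar(x$primerset_name))
                paste0(" (", x$primerset_name, ")") else "",
              length(x$rows), x$tail_len))
  invisible(x)
}

#' Per-column Shannon entropy of a tail stack
#'
#' `H_j = -sum_b f_bj log2 f_bj` over the unambiguous bases A/C/G/T only
#' (with 0 log 0 := 0), so 0 <= H_j <= 2 bits and H_j = 0 iff the column
#' is monomorphic among retained symbols. Columns with no unambiguous
#' symbol are reported as NA.
#'
#' @param stack A `tail_stack`.
#' @return An object of class `entropy_profile`: list with `H` (numeric
#'   vector of per-column entropies, bits) and `n_rows`.
#' @export
column_entropy <- function(stack) {
  stopifnot(inherits(stack, "tail_stack"))
  H <- apply(stack$freqs, 2L, function(f) {
    if (anyNA(f)) return(NA_real_)
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  structure(list(H = unname(H), n_rows = length(stack$rows)),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("Entropy profile over %d columns (%d rows): mean %.3f bits, max %.3f bits\n",
              length(x$H), x$n_rows, mean(x$H, na.rm = TRUE),
              max(x$H, na.rm = TRUE)))
  invisible(x)
}

# Per-column IUPAC consensus: majority base if its frequency reaches
# min_freq, otherwise the minimal code covering every base at frequency
# >= minor_freq. Columns without unambiguous symbols give N.
.consensus_symbol <- function(f, min_freq, minor_freq) {
  if (anyNA(f)) return("N")
  bases <- names(f)
  top <- which.max(f)
  if (f[top] >= min_freq) return(bases[top])
  cover <- bases[f >= minor_freq]
  if (length(cover) == 0L) cover <- bases[top]
  .cover_code(cover)
}

# Forward-strand column range of the candidate window of length L:
# the first `overlap_len` columns of the reverse-primer site plus the
# (L - overlap_len) columns immediately 5' of the site.
.window_cols <- function(tail_len, rev_len, L, overlap_len) {
  site_start <- tail_len - rev_len + 1L
  wstart <- site_start - (L - overlap_len)
  wend <- site_start + overlap_len - 1L
  if (wstart < 1L) {
    stop(sprintf("stack rows too short for a length-%d window", L),
         call. = FALSE)
  }
  seq(wstart, wend)
}

#' Enumerate blocking-primer candidates from a host tail stack
#'
#' For each candidate length L in `[min_len, max_len]` the forward-strand
#' window consists of the first `overlap_len` bases of the reverse-primer
#' binding site plus the `L - overlap_len` bases immediately 5' of it. A
#' per-column IUPAC consensus of the host stack over the window is reverse
#' complemented, so the candidate is written 5'->3' in reverse-primer
#' orientation and its 5' prefix overlaps the reverse primer's 3' end by
#' exactly `overlap_len` bases. Candidates that are mostly N (> 50%) or
#' whose melting temperature differs from the mean of the two primer Tm
#' values by more than `tm_tolerance` are rejected.
#'
#' @param stack Host `tail_stack` (rows must end on the reverse-primer
#'   site).
#' @param primers The targeted [primer_set].
#' @param min_len,max_len Candidate length bounds (defaults 20 and 29;
#'   lengths of 30 or more require `allow_long = TRUE`).
#' @param overlap_len Bases shared with the reverse primer's 3' end
#'   (default 10).
#' @param tm_tolerance Maximum |Tm(candidate) - mean primer Tm| in degrees
#'   Celsius (default 5).
#' @param consensus_min_freq Majority-base frequency above which a column
#'   stays unambiguous (default 0.9).
#' @param minor_freq Frequency above which a base enters a degenerate
#'   consensus code (default 0.1).
#' @param allow_long Permit candidates of 30 nt or longer (default FALSE).
#' @return A data.frame of class `blocking_candidates` with columns `seq`,
#'   `length`, `overlap_len`, `tm`, `mean_entropy` (mean host tail entropy
#'   over the window, bits).
#' @export
enumerate_candidates <- function(stack, primers, min_len = 20L,
                                 max_len = 29L, overlap_len = 10L,
                                 tm_tolerance = 5, consensus_min_freq = 0.9,
                                 minor_freq = 0.1, allow_long = FALSE) {
  stopifnot(inherits(stack, "tail_stack"), inherits(primers, "primer_set"))
  if (max_len >= 30L && !allow_long) {
    stop("candidates of 30 nt or longer require allow_long = TRUE",
         call. = FALSE)
  }
  rev_len <- nchar(primers$reverse)
  target_tm <- mean(c(melting_temperature(primers$forward),
                      melting_temperature(primers$reverse)))
  prof <- column_entropy(stack)
  out <- list()
  for (L in seq(min_len, max_len)) {
    cols <- .window_cols(stack$tail_len, rev_len, L, overlap_len)
    cons <- vapply(cols, function(j)
      .consensus_symbol(stats::setNames(stack$freqs[, j],
                                        rownames(stack$freqs)),
                        consensus_min_freq, minor_freq), character(1L))
    if (mean(cons == "N") > 0.5) next
    cand <- revcomp(paste(cons, collapse = ""))
    tm <- melting_temperature(cand)
    if (abs(tm - target_tm) > tm_tolerance) next
    out[[length(out) + 1L]] <- data.frame(
      seq = cand, length = L, overlap_len = overlap_len, tm = tm,
      mean_entropy = mean(prof$H[cols], na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(seq = character(0L), length = integer(0L),
               overlap_len = integer(0L), tm = numeric(0L),
               mean_entropy = numeric(0L), stringsAsFactors = FALSE)
  class(res) <- c("blocking_candidates", "data.frame")
  attr(res, "target_tm") <- target_tm
  res
}

#' Rank blocking-primer candidates by in silico specificity
#'
#' Scores each candidate against the host and off-target databases
#' (fraction of amplifiable records blocked, see [is_blocked]) and orders
#' candidates lexicographically: maximal host blocked fraction, then
#' minimal off-target blocked fraction, then shorter length. The sort is
#' stable, so ties keep enumeration order.
#'
#' @param cands A `blocking_candidates` data.frame.
#' @param primers The targeted [primer_set].
#' @param host,offtarget Host and off-target [ref_db] objects.
#' @param criteria A [blocking_criteria] object.
#' @return The candidates data.frame with columns `host_blocked` and
#'   `offtarget_blocked` added, ordered best-first.
#' @export
rank_candidates <- function(cands, primers, host, offtarget,
                            criteria = blocking_criteria()) {
  if (nrow(cands) == 0L) stop("no candidates to rank", call. = FALSE)
  score <- function(blocker, db) {
    s <- .blocked_counts(db, primers, blocker, criteria)
    if (s$n_total == 0L) 0 else s$n_blocked / s$n_total
  }
  cands$host_blocked <- vapply(cands$seq, score, numeric(1L), db = host,
                               USE.NAMES = FALSE)
  cands$offtarget_blocked <- vapply(cands$seq, score, numeric(1L),
                                    db = offtarget, USE.NAMES = FALSE)
  ord <- order(-cands$host_blocked, cands$offtarget_blocked, cands$length,
               method = "radix")
  res <- cands[ord, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("blocking_candidates", "data.frame")
  res
}

#' Design blocking primers against a host database
#'
#' End-to-end designer: extracts amplicons from the host and off-target
#' databases, stacks the host amplicon 3'-tails, profiles per-column
#' entropy for both sets, enumerates candidates under the
#' length/overlap/Tm constraints and ranks them by in silico specificity.
#'
#' @param host,offtarget Host and off-target [ref_db] objects (already
#'   restricted to amplifiable sequences or not; non-amplifiable records
#'   are ignored).
#' @param primers The targeted [primer_set].
#' @param tail_len Tail length stacked (default 40).
#' @param max_mismatch Mismatch budget for amplicon extraction (default 0).
#' @param criteria [blocking_criteria] used for specificity scoring.
#' @param ... Passed to [enumerate_candidates].
#' @return An object of class `blocking_design` with elements `primers`,
#'   `candidates` (ranked), `best` (top row), `host_entropy`,
#'   `offtarget_entropy`, `n_host`, `n_offtarget`, `tail_len`.
#' @examples
#' fam <- synth_host_family(n_host = 12, tail_divergence = 0, seed = 4)
#' off <- synth_offtarget_db(group_sizes = c(Rhizaria = 8), seed = 5)
#' d <- design_blocking_primers(fam$db, off$db, fam$primers)
#' print(d)
#' @export
design_blocking_primers <- function(host, offtarget, primers,
                                    tail_len = 40L, max_mismatch = 0L,
                                    criteria = blocking_criteria(), ...) {
  host_amp <- extract_amplicons(host, primers, max_mismatch = max_mismatch)
  if (nrow(host_amp) == 0L) stop("no amplifiable host sequences",
                                 call. = FALSE)
  off_amp <- extract_amplicons(offtarget, primers,
                               max_mismatch = max_mismatch)
  host_stack <- extract_tail_stack(host_amp, tail_len = tail_len,
                                   primerset_name = primers$name)
  off_stack <- if (nrow(off_amp) > 0L) {
    extract_tail_stack(off_amp, tail_len = tail_len,
                       primerset_name = primers$name)
  } else NULL
  cands <- enumerate_candidates(host_stack, primers, ...)
  if (nrow(cands) == 0L) stop("no candidate satisfied the constraints",
                              call. = FALSE)
  ranked <- rank_candidates(cands, primers, host, offtarget, criteria)
  structure(
    list(primers = primers, candidates = ranked, best = ranked[1L, ],
         host_entropy = column_entropy(host_stack),
         offtarget_entropy = if (!is.null(off_stack))
           column_entropy(off_stack) else NULL,
         n_host = nrow(host_amp), n_offtarget = nrow(off_amp),
         tail_len = tail_len, criteria = criteria),
    class = "blocking_design")
}

#' @export
print.blocking_design <- function(x, ...) {
  cat(sprintf("Blocking-primer design for %s (%d host / %d off-target amplicons)\n",
              x$primers$name, x$n_host, x$n_offtarget))
  b <- x$best
  cat(sprintf("  best candidate: %s\n", b$seq))
  cat(sprintf("  length %d nt, overlap %d nt, Tm %.1f C\n",
              b$length, b$overlap_len, b$tm))
  cat(sprintf("  host blocked %.1f%%, off-target blocked %.1f%%\n",
              100 * b$host_blocked, 100 * b$offtarget_blocked))
  invisible(x)
}

#' @export
summary.blocking_design <- function(object, ...) {
  cat(sprintf("Blocking-primer design for %s\n", object$primers$name))
  cat(sprintf("  %d candidate(s) over tail length %d\n",
              nrow(object$candidates), object$tail_len))
  print(as.data.frame(object$candidates))
  invisible(object$candidates)
}

#' Plot entropy profiles of a blocking design
#'
#' Per-column Shannon entropy (bits) of the host tail stack, with the
#' off-target profile overlaid when available. Low host entropy with high
#' off-target entropy marks columns where a blocker can discriminate.
#'
#' @param x A `blocking_design`.
#' @param ... Passed to [graphics::plot].
#' @export
plot.blocking_design <- function(x, ...) {
  H <- x$host_entropy$H
  graphics::plot(seq_along(H), H, type = "h", lwd = 3, col = "firebrick",
                 xlab = "tail column", ylab = "entropy (bits)",
                 ylim = c(0, 2), ...)
  if (!is.null(x$offtarget_entropy)) {
    graphics::lines(seq_along(x$offtarget_entropy$H),
                    x$offtarget_entropy$H, type = "p", pch = 1,
                    col = "steelblue")
    graphics::legend("topleft", legend = c("host", "off-target"),
                     col = c("firebrick", "steelblue"),
                     lty = c(1, NA), pch = c(NA, 1), bty = "n")
  }
  invisible(x)
}
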