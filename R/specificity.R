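# In silico specificity: does a blocker "block" a sequence, and per-taxon
# blocked-fraction reports.

#' Criteria deciding when a blocker blocks a sequence
#'
#' @param max_mismatch Degenerate-aware mismatches tolerated between the
#'   blocker's annealing window and the record (default 0, the strictest
#'   reading of "matched").
#' @param require_full_site Require the whole annealing window to lie
#'   inside the record (default TRUE); if FALSE, windows truncated at the
#'   record boundary are compared over their overlap.
#' @param overlap_len Bases of the blocker overlapping the reverse
#'   primer's 3' end; positions the annealing window relative to the
#'   reverse-primer site (default 10).
#' @param amp_max_mismatch Mismatch budget used to decide amplifiability
#'   (default 0).
#' @return An object of class `blocking_criteria`.
#' @export
blocking_criteria <- function(max_mismatch = 0L, require_full_site = TRUE,
                              overlap_len = 10L, amp_max_mismatch = 0L) {
  stopifnot(max_mismatch >= 0L, overlap_len >= 1L, amp_max_mismatch >= 0L)
  structure(list(max_mismatch = as.integer(max_mismatch),
                 require_full_site = isTRUE(require_full_site),
                 overlap_len = as.integer(overlap_len),
                 amp_max_mismatch = as.integer(amp_max_mismatch)),
            class = "blocking_criteria")
}

#' Is a record blocked by a blocking primer?
#'
#' The blocker's annealing site is the forward-strand window whose reverse
#' complement the blocker equals: it is positioned by the amplicon's
#' reverse-primer site, covering the first `overlap_len` bases of that
#' site and extending `nchar(blocker) - overlap_len` bases 5' of it. The
#' record is blocked iff that window matches the reverse complement of the
#' blocker with at most `max_mismatch` degenerate-aware mismatches.
#' Records that are not amplifiable by the primer set return FALSE.
#'
#' @param rec A list with `id` and `seq`, or a single-record [ref_db].
#' @param primers A [primer_set].
#' @param blocker Blocking-primer IUPAC string (5'->3', reverse-primer
#'   orientation).
#' @param criteria A [blocking_criteria].
#' @return Logical scalar.
#' @export
is_blocked <- function(rec, primers, blocker,
                       criteria = blocking_criteria()) {
  stopifnot(inherits(criteria, "blocking_criteria"))
  if (inherits(rec, "ref_db")) {
    stopifnot(length(rec) == 1L)
    rec <- list(id = rec$ids[1L], seq = rec$seqs[1L])
  }
  blocker <- normalize_seq(blocker, "blocking primer")
  blen <- nchar(blocker)
  if (blen < criteria$overlap_len) {
    stop("blocker shorter than the overlap contract", call. = FALSE)
  }
  hit <- tryCatch(
    extract_amplicon(rec, primers,
                     max_mismatch = criteria$amp_max_mismatch),
    no_amplicon = function(e) NULL)
  if (is.null(hit)) return(FALSE)
  s <- hit$rev_site_start
  wstart <- s - (blen - criteria$overlap_len)
  wend <- s + criteria$overlap_len - 1L
  site <- revcomp(blocker)
  if (wstart < 1L) {
    if (criteria$require_full_site) return(FALSE)
    site <- substr(site, 2L - wstart, blen)
    wstart <- 1L
  }
  window <- substr(rec$seq, wstart, wend)
  count_mismatches(site, window) <= criteria$max_mismatch
}

# Blocked/total counts among amplifiable records of a database.
.blocked_counts <- function(db, primers, blocker, criteria) {
  amp <- logical(length(db))
  blk <- logical(length(db))
  for (i in seq_along(db$ids)) {
    rec <- list(id = db$ids[i], seq = db$seqs[i])
    hit <- tryCatch(
      extract_amplicon(rec, primers,
                       max_mismatch = criteria$amp_max_mismatch),
      no_amplicon = function(e) NULL)
    if (is.null(hit)) next
    amp[i] <- TRUE
    blk[i] <- is_blocked(rec, primers, blocker, criteria)
  }
  list(n_total = sum(amp), n_blocked = sum(blk), amplifiable = amp,
       blocked = blk)
}

#' Per-taxon-group specificity report for a blocking primer
#'
#' Reports, for the host database (one row) and for each taxon group of
#' the off-target database, how many amplifiable sequences the blocker
#' blocks. Off-target records are grouped either by the taxonomy label at
#' rank `group_rank`, or by an explicit label-to-group map (`group_map`, a
#' named character vector matched against every rank label) for reports
#' that mix ranks. Non-amplifiable records are excluded from denominators;
#' groups with no amplifiable record are omitted. Rows are sorted by
#' blocked fraction, descending.
#'
#' @param blocker Blocking-primer IUPAC string.
#' @param primers A [primer_set].
#' @param host,offtarget [ref_db] objects; `host` must be nonempty.
#' @param group_rank Integer taxonomy rank used to label off-target groups
#'   (default 2).
#' @param group_map Optional named character vector `label -> group`
#'   overriding `group_rank`.
#' @param criteria A [blocking_criteria].
#' @param host_label Label of the host row (defaults to the host database
#'   label).
#' @return A data.frame of class `specificity_report` with columns
#'   `group`, `n_total`, `n_blocked`, `fraction_blocked`.
#' @export
specificity_report <- function(blocker, primers, host, offtarget,
                               group_rank = 2L, group_map = NULL,
                               criteria = blocking_criteria(),
                               host_label = NULL) {
  stopifnot(inherits(host, "ref_db"), inherits(offtarget, "ref_db"))
  if (length(host) == 0L) stop("host database is empty", call. = FALSE)
  if (is.null(host_label)) host_label <- host$label
  hs <- .blocked_counts(host, primers, blocker, criteria)
  rows <- data.frame(group = host_label, n_total = hs$n_total,
                     n_blocked = hs$n_blocked, stringsAsFactors = FALSE)
  if (length(offtarget) > 0L) {
    os <- .blocked_counts(offtarget, primers, blocker, criteria)
    grp <- vapply(offtarget$taxonomy, function(tax) {
      if (!is.null(group_map)) {
        hitlab <- tax[tax %in% names(group_map)]
        if (length(hitlab)) return(unname(group_map[hitlab[1L]]))
        return("other")
      }
      if (length(tax) >= group_rank) tax[[group_rank]] else "unclassified"
    }, character(1L))
    for (g in unique(grp)) {
      sel <- grp == g & os$amplifiable
      if (!any(sel)) next
      rows <- rbind(rows, data.frame(group = g, n_total = sum(sel),
                                     n_blocked = sum(os$blocked[sel]),
                                     stringsAsFactors = FALSE))
    }
  }
  rows$fraction_blocked <- ifelse(rows$n_total > 0,
                                  rows$n_blocked / rows$n_total, NA_real_)
  rows <- rows[order(-rows$fraction_blocked, rows$group,
                     method = "radix"), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "blocker") <- blocker
  class(rows) <- c("specificity_report", "data.frame")
  rows
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf("In silico specificity of blocker %s\n", attr(x, "blocker")))
  df <- as.data.frame(x)
  df$percent_blocked <- sprintf("%.1f", 100 * df$fraction_blocked)
  print(df[, c("group", "n_total", "n_blocked", "percent_blocked")],
        row.names = FALSE)
  invisible(x)
}
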