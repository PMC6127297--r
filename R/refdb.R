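#' Construct a reference sequence database
#'
#' An ordered collection of taxonomy-annotated nucleotide sequences, the
#' universe all design steps operate on. Sequences are normalized at
#' construction (uppercase, U -> T) and checked against the IUPAC
#' alphabet; ids must be unique.
#'
#' @param ids Character vector of unique, nonempty record ids.
#' @param seqs Character vector of nucleotide strings (same length as `ids`).
#' @param taxonomy List of character vectors (ranked taxonomy paths), one
#'   per record; may contain empty vectors.
#' @param label Database label used in messages and derived labels.
#' @return An object of class `ref_db`.
#' @export
ref_db <- function(ids, seqs, taxonomy = NULL, label = "db") {
  ids <- as.character(ids)
  seqs <- as.character(seqs)
  if (length(ids) != length(seqs)) {
    stop("ids and seqs must have the same length", call. = FALSE)
  }
  if (any(!nzchar(ids))) stop("record ids must be nonempty", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate record id: ", dup[1L], call. = FALSE)
  }
  if (is.null(taxonomy)) taxonomy <- rep(list(character(0L)), length(ids))
  if (length(taxonomy) != length(ids)) {
    stop("taxonomy must have one entry per record", call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop("record ", ids[which(!nzchar(seqs))[1L]], " has an empty sequence",
         call. = FALSE)
  }
  seqs <- unname(mapply(normalize_seq, seqs, sprintf("record %s", ids)))
  structure(
    list(ids = ids, seqs = seqs, taxonomy = unname(taxonomy), label = label),
    class = "ref_db"
  )
}

#' @export
length.ref_db <- function(x) length(x$ids)

#' @export
print.ref_db <- function(x, ...) {
  cat(sprintf("Reference database '%s': %d records\n", x$label, length(x)))
  if (length(x)) {
    n <- min(3L, length(x))
    for (i in seq_len(n)) {
      cat(sprintf("  %s [%s] %d nt\n", x$ids[i],
                  paste(x$taxonomy[[i]], collapse = ";"), nchar(x$seqs[i])))
    }
    if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  }
  invisible(x)
}

#' @export
`[.ref_db` <- function(x, i) {
  idx <- seq_along(x$ids)
  names(idx) <- x$ids
  i <- if (is.character(i)) unname(idx[i]) else idx[i]
  ref_db(x$ids[i], x$seqs[i], x$taxonomy[i], label = x$label)
}

#' Read a FASTA reference database with Silva-style taxonomy headers
#'
#' Headers are parsed as `id<whitespace>rank1;rank2;...`: the token before
#' the first whitespace is the record id, the remainder (split on
#' `taxonomy_delimiter`) is the ranked taxonomy path. Sequences are
#' normalized (uppercase, U -> T) and validated against the IUPAC alphabet.
#'
#' @param path FASTA file path.
#' @param taxonomy_delimiter Delimiter between taxonomy ranks (default ";").
#' @param label Database label (defaults to the file name).
#' @return A [ref_db] object.
#' @export
read_fasta_db <- function(path, taxonomy_delimiter = ";",
                          label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(ref_db(character(0L), character(0L), list(), label = label))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  rest <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  taxonomy <- lapply(rest, function(r) {
    if (!nzchar(r)) return(character(0L))
    parts <- trimws(strsplit(r, taxonomy_delimiter, fixed = TRUE)[[1L]])
    parts[nzchar(parts)]
  })
  ref_db(ids, as.character(set), taxonomy, label = label)
}

#' Write a reference database to FASTA
#'
#' Headers are `id taxonomy` with ranks joined by `taxonomy_delimiter`;
#' sequence lines are wrapped at `width` characters.
#'
#' @param db A [ref_db].
#' @param path Output file path.
#' @param taxonomy_delimiter Rank delimiter (default ";").
#' @param width Line width (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta_db <- function(db, path, taxonomy_delimiter = ";", width = 80L) {
  stopifnot(inherits(db, "ref_db"))
  headers <- vapply(seq_along(db$ids), function(i) {
    tax <- paste(db$taxonomy[[i]], collapse = taxonomy_delimiter)
    if (nzchar(tax)) paste(db$ids[i], tax) else db$ids[i]
  }, character(1L))
  set <- Biostrings::BStringSet(db$seqs)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Partition a database into host and off-target (exclusion-free) sets
#'
#' The host set contains records whose taxonomy includes `host_taxon` as an
#' exact label at any rank; the off-target set contains records whose
#' taxonomy includes `exclude_taxon` at no rank. Matching is exact
#' whole-label and case-sensitive. With the default Scleractinia/Metazoa
#' pair the host taxon is nested under the excluded taxon, so the two sets
#' are disjoint. Records in neither set are dropped, with a message giving
#' the count; records with empty taxonomy are retained conservatively in
#' the off-target set (they name the excluded taxon at no rank).
#'
#' @param db A [ref_db].
#' @param host_taxon Taxon label defining the host set (default
#'   "Scleractinia").
#' @param exclude_taxon Taxon label whose carriers are removed from the
#'   off-target set (default "Metazoa").
#' @return List with elements `host` and `offtarget`, both [ref_db].
#' @export
partition_host_offtarget <- function(db, host_taxon = "Scleractinia",
                                     exclude_taxon = "Metazoa") {
  stopifnot(inherits(db, "ref_db"))
  if (!nzchar(host_taxon) || !nzchar(exclude_taxon)) {
    stop("host_taxon and exclude_taxon must be nonempty", call. = FALSE)
  }
  if (length(db) == 0L) stop("cannot partition an empty database",
                             call. = FALSE)
  is_host <- vapply(db$taxonomy, function(t) host_taxon %in% t, logical(1L))
  is_free <- vapply(db$taxonomy, function(t) !(exclude_taxon %in% t),
                    logical(1L))
  if (!any(is_host)) {
    warning(sprintf("host taxon '%s' not found in any record", host_taxon),
            call. = FALSE)
  }
  n_empty_tax <- sum(is_free & vapply(db$taxonomy, length, integer(1L)) == 0L)
  if (n_empty_tax > 0L) {
    message(sprintf(
      "%d record(s) with empty taxonomy retained in the off-target set",
      n_empty_tax))
  }
  dropped <- sum(!is_host & !is_free)
  if (dropped > 0L) {
    message(sprintf("%d record(s) in neither set dropped", dropped))
  }
  host <- ref_db(db$ids[is_host], db$seqs[is_host], db$taxonomy[is_host],
                 label = paste0(db$label, "|", host_taxon))
  off <- ref_db(db$ids[is_free], db$seqs[is_free], db$taxonomy[is_free],
                label = paste0(db$label, "|", exclude_taxon, "-free"))
  list(host = host, offtarget = off)
}

#' Restrict a database to sequences amplifiable by a primer set
#'
#' Keeps records for which [extract_amplicon] succeeds at the given
#' mismatch budget, preserving input order. Monotone in `max_mismatch`:
#' every record kept at budget m is kept at m + 1.
#'
#' @param db A [ref_db].
#' @param primers A [primer_set].
#' @param max_mismatch Per-primer mismatch budget (default 0, the strictest
#'   reading of "matched").
#' @param both_strands Also scan the reverse strand (default FALSE for
#'   pre-oriented rRNA databases).
#' @return A [ref_db] labeled `<label>|<primer set name>`.
#' @export
filter_amplifiable <- function(db, primers, max_mismatch = 0L,
                               both_strands = FALSE) {
  stopifnot(inherits(db, "ref_db"), inherits(primers, "primer_set"))
  keep <- vapply(seq_along(db$ids), function(i) {
    hit <- tryCatch(
      extract_amplicon(list(id = db$ids[i], seq = db$seqs[i]), primers,
                       max_mismatch = max_mismatch,
                       both_strands = both_strands),
      no_amplicon = function(e) NULL)
    !is.null(hit)
  }, logical(1L))
  ref_db(db$ids[keep], db$seqs[keep], db$taxonomy[keep],
         label = paste0(db$label, "|", primers$name))
}
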