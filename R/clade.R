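# Clade annotation of environmental OTUs by identity-threshold clustering
# against reference panels (the Symbiodinium procedure): pairwise identity
# on a shared alignment, complete-linkage clustering at a similarity
# cutoff, threshold scanning for the cutoff that separates reference
# clades, and co-clustering annotation.

#' Pairwise identity of two aligned sequences
#'
#' Identity = matches / compared columns over the region where both
#' sequences have begun and not yet ended (leading/trailing gap overhangs
#' are excluded, as after trimming an alignment at each extremity).
#' Within that region, columns gapped in both sequences are skipped and
#' columns gapped in exactly one count as mismatches. Symbol comparison is
#' exact (case-insensitive).
#'
#' @param a,b Aligned sequences of equal length; gap character "-" (or ".").
#' @return Identity in \[0, 1\].
#' @examples
#' pairwise_identity("--ACGT", "TTACGT") # 1: overhang excluded
#' @export
pairwise_identity <- function(a, b) {
  ca <- .seq_chars(toupper(a))
  cb <- .seq_chars(toupper(b))
  if (length(ca) != length(cb)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  gap <- function(x) x == "-" | x == "."
  ga <- gap(ca); gb <- gap(cb)
  ra <- range(which(!ga)); rb <- range(which(!gb))
  lo <- max(ra[1L], rb[1L]); hi <- min(ra[2L], rb[2L])
  if (lo > hi) stop("no overlapping aligned region", call. = FALSE)
  idx <- lo:hi
  both_gap <- ga[idx] & gb[idx]
  idx <- idx[!both_gap]
  if (length(idx) == 0L) stop("zero compared columns", call. = FALSE)
  matches <- sum(!ga[idx] & !gb[idx] & ca[idx] == cb[idx])
  matches / length(idx)
}

#' Pairwise identity matrix of a set of aligned sequences
#'
#' @param seqs Named character vector of aligned sequences (one shared
#'   alignment length).
#' @return Symmetric matrix of identities with unit diagonal, dimnames =
#'   sequence names.
#' @export
identity_matrix <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named", call. = FALSE)
  }
  n <- length(seqs)
  m <- diag(1, n)
  dimnames(m) <- list(names(seqs), names(seqs))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        m[i, j] <- m[j, i] <- pairwise_identity(seqs[[i]], seqs[[j]])
      }
    }
  }
  m
}

#' Cluster sequences at a similarity threshold
#'
#' Agglomerative clustering on distance 1 - identity with cutoff
#' 1 - threshold: two clusters merge while their linkage distance is at
#' most the cutoff. Complete linkage (furthest neighbor) by default, so
#' every within-cluster pair is guaranteed to meet the threshold; average
#' linkage is available. Labels are processed in lexicographic order for
#' deterministic tie handling; cluster ids are renumbered by first
#' appearance in the input label order.
#'
#' @param idm Identity matrix (see [identity_matrix]).
#' @param threshold Similarity threshold in \[0.5, 1\].
#' @param linkage "complete" (default) or "average".
#' @return Named integer vector: cluster membership per label, in the
#'   input label order.
#' @export
cluster_at <- function(idm, threshold, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  stopifnot(threshold >= 0.5, threshold <= 1)
  labels <- rownames(idm)
  if (length(labels) == 1L) {
    return(stats::setNames(1L, labels))
  }
  ord <- order(labels, method = "radix")
  d <- stats::as.dist(1 - idm[ord, ord, drop = FALSE])
  hc <- stats::hclust(d, method = linkage)
  cutoff <- (1 - threshold) + 1e-9  # inclusive merge at exact cutoff
  part <- stats::cutree(hc, h = cutoff)
  part <- part[labels]  # back to input order
  stats::setNames(match(part, unique(part)), labels)
}

#' Lowest similarity threshold separating reference clades
#'
#' Scans thresholds in ascending order and returns the lowest at which
#' clustering the reference sequences yields exactly one cluster per clade
#' with no cluster mixing clades (the criterion under which environmental
#' sequences were annotated: all reference clades fall into distinct
#' groups). `pick = "highest"` returns the highest qualifying threshold
#' instead. Returns NA (with a warning) when no scanned threshold
#' separates the clades.
#'
#' @param idm Identity matrix of the reference sequences.
#' @param clades Named character vector: clade label per reference id.
#' @param thresholds Ascending thresholds to scan (default 0.90 to 0.99 by
#'   0.01).
#' @param linkage Passed to [cluster_at].
#' @param pick "lowest" (default) or "highest" qualifying threshold.
#' @return Numeric threshold, or NA if none qualifies.
#' @export
find_separation_threshold <- function(idm, clades,
                                      thresholds = seq(0.90, 0.99, by = 0.01),
                                      linkage = "complete",
                                      pick = c("lowest", "highest")) {
  pick <- match.arg(pick)
  clades <- clades[rownames(idm)]
  if (length(unique(clades)) < 2L) {
    stop("at least two clades are required", call. = FALSE)
  }
  thresholds <- sort(thresholds)
  qualifying <- numeric(0L)
  for (t in thresholds) {
    part <- cluster_at(idm, t, linkage = linkage)
    tab <- table(part, clades)
    ok <- all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L)
    if (ok) qualifying <- c(qualifying, t)
  }
  if (length(qualifying) == 0L) {
    warning("no scanned threshold separates the clades", call. = FALSE)
    return(NA_real_)
  }
  if (pick == "lowest") min(qualifying) else max(qualifying)
}

#' Annotate query OTUs by co-clustering with reference clades
#'
#' References and queries are clustered jointly at `threshold`; a query
#' inherits a clade label iff its cluster contains references of exactly
#' one clade. Clusters with no reference, or (below a separating
#' threshold) with references of several clades, yield "unassigned".
#'
#' @param otu_seqs Named character vector of aligned query sequences.
#' @param ref_seqs Named character vector of aligned reference sequences
#'   (same alignment length as the queries).
#' @param ref_clades Named character vector: clade per reference id.
#' @param threshold Similarity threshold (typically from
#'   [find_separation_threshold]).
#' @param linkage Passed to [cluster_at].
#' @return Data.frame with columns `otu_id`, `clade`, `cluster`.
#' @export
annotate_by_cocluster <- function(otu_seqs, ref_seqs, ref_clades,
                                  threshold, linkage = "complete") {
  if (length(ref_seqs) == 0L) {
    warning("no reference sequences supplied; all OTUs unassigned",
            call. = FALSE)
    return(data.frame(otu_id = names(otu_seqs),
                      clade = rep("unassigned", length(otu_seqs)),
                      cluster = NA_integer_, stringsAsFactors = FALSE))
  }
  all_seqs <- c(ref_seqs, otu_seqs)
  if (anyDuplicated(names(all_seqs))) {
    stop("reference and OTU ids must be distinct", call. = FALSE)
  }
  part <- cluster_at(identity_matrix(all_seqs), threshold,
                     linkage = linkage)
  ref_part <- part[names(ref_seqs)]
  clade_of_cluster <- vapply(unique(part), function(k) {
    cl <- unique(ref_clades[names(ref_part)[ref_part == k]])
    cl <- cl[!is.na(cl)]
    if (length(cl) == 1L) cl else "unassigned"
  }, character(1L))
  names(clade_of_cluster) <- as.character(unique(part))
  q <- part[names(otu_seqs)]
  data.frame(otu_id = names(otu_seqs),
             clade = unname(clade_of_cluster[as.character(q)]),
             cluster = unname(q), stringsAsFactors = FALSE)
}
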