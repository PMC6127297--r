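# Community statistics for blocked-primer metabarcoding data: OTU-table
# filters, genus aggregation, Pielou evenness, Fisher region association
# with Bonferroni correction, patristic distances, Mantel tests.

#' Construct an OTU count table
#'
#' @param counts Integer matrix, samples x OTUs, with dimnames.
#' @param regions Optional named character vector: region label per sample
#'   (names = sample ids).
#' @param taxonomy Optional list of character vectors, one ranked taxonomy
#'   path per OTU.
#' @param coverage Optional numeric vector in \[0, 1\]: annotation (blast)
#'   coverage per OTU.
#' @return An object of class `otu_table_bp`.
#' @export
otu_table_bp <- function(counts, regions = NULL, taxonomy = NULL,
                         coverage = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts)))) {
    stop("counts must have sample row names and OTU column names",
         call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!is.null(regions)) {
    regions <- regions[rownames(counts)]
    if (anyNA(regions)) stop("every sample needs a region label",
                             call. = FALSE)
  }
  if (!is.null(taxonomy) && length(taxonomy) != ncol(counts)) {
    stop("taxonomy must have one entry per OTU", call. = FALSE)
  }
  if (!is.null(coverage)) {
    coverage <- unname(coverage)
    if (length(coverage) != ncol(counts)) {
      stop("coverage must have one value per OTU", call. = FALSE)
    }
  }
  structure(list(counts = counts, regions = regions,
                 taxonomy = taxonomy, coverage = coverage),
            class = "otu_table_bp")
}

#' @export
print.otu_table_bp <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$regions)) {
    cat("  regions:", paste(sprintf("%s (%d)", names(table(x$regions)),
                                    table(x$regions)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Drop OTUs with low annotation coverage
#'
#' Keeps OTUs whose annotation (blast) coverage is at least
#' `min_coverage`; OTUs annotated with coverage below 90% are removed
#' under the default.
#'
#' @param table An [otu_table_bp] with `coverage` set for every OTU.
#' @param min_coverage Inclusive lower bound (default 0.90).
#' @return Filtered [otu_table_bp].
#' @export
filter_coverage <- function(table, min_coverage = 0.90) {
  stopifnot(inherits(table, "otu_table_bp"))
  if (is.null(table$coverage)) {
    stop("OTU table has no coverage annotation", call. = FALSE)
  }
  if (anyNA(table$coverage)) {
    stop("missing coverage for OTU ",
         colnames(table$counts)[which(is.na(table$coverage))[1L]],
         call. = FALSE)
  }
  keep <- table$coverage >= min_coverage
  if (!any(keep)) warning("no OTU passes the coverage filter",
                          call. = FALSE)
  otu_table_bp(table$counts[, keep, drop = FALSE], table$regions,
               if (!is.null(table$taxonomy)) table$taxonomy[keep],
               table$coverage[keep])
}

#' Presence/absence matrix under a minimum-read rule
#'
#' An OTU is considered present in a sample iff it has at least
#' `min_reads` sequences there (default 3).
#'
#' @param table An [otu_table_bp] or a counts matrix.
#' @param min_reads Minimum reads for presence (default 3, must be >= 1).
#' @return Logical matrix, samples x OTUs.
#' @export
presence_filter <- function(table, min_reads = 3L) {
  stopifnot(min_reads >= 1L)
  counts <- if (inherits(table, "otu_table_bp")) table$counts else
    as.matrix(table)
  counts >= min_reads
}

#' Aggregate OTU counts at the genus rank
#'
#' Sums counts per (sample, genus). The genus of an OTU is the taxonomy
#' label at `genus_rank` (default: the last rank of its path); OTUs with
#' no genus fall into an "unclassified" bucket. Taxonomy is truncated at
#' the genus.
#'
#' @param table An [otu_table_bp] with taxonomy.
#' @param genus_rank Integer rank index, or NULL for the last rank.
#' @return An [otu_table_bp] whose columns are genera.
#' @export
aggregate_genus <- function(table, genus_rank = NULL) {
  stopifnot(inherits(table, "otu_table_bp"))
  if (ncol(table$counts) == 0L) return(table)
  if (is.null(table$taxonomy)) {
    stop("OTU table has no taxonomy", call. = FALSE)
  }
  genus <- vapply(table$taxonomy, function(tax) {
    g <- if (is.null(genus_rank)) {
      if (length(tax)) tax[[length(tax)]] else NA_character_
    } else if (length(tax) >= genus_rank) tax[[genus_rank]] else
      NA_character_
    if (is.na(g) || !nzchar(g)) "unclassified" else g
  }, character(1L))
  agg <- t(rowsum(t(table$counts), group = genus))
  # keep first-appearance order of genera
  agg <- agg[, unique(genus), drop = FALSE]
  tax <- lapply(unique(genus), function(g) {
    full <- table$taxonomy[[match(g, genus)]]
    if (g == "unclassified") return("unclassified")
    full[seq_len(match(g, full))]
  })
  otu_table_bp(agg, table$regions, tax, coverage = NULL)
}

#' Pielou's evenness
#'
#' `J = H' / ln S` with `H' = -sum p_i ln p_i` over taxa with positive
#' abundance and `S` their number. Scale-invariant; defined only for at
#' least two positive taxa, where it lies in (0, 1].
#'
#' @param abundances Non-negative numeric vector.
#' @return Evenness J.
#' @examples
#' pielou_evenness(c(10, 10, 10, 10)) # 1
#' @export
pielou_evenness <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be non-negative",
                                call. = FALSE)
  x <- abundances[abundances > 0]
  S <- length(x)
  if (S < 2L) stop("evenness undefined for fewer than 2 positive taxa",
                   call. = FALSE)
  p <- x / sum(x)
  -sum(p * log(p)) / log(S)
}

#' Fisher exact tests of taxon-region association
#'
#' For each taxon, builds the 2x2 table of samples where the taxon is
#' present/absent by region and computes the two-sided Fisher exact
#' p-value (via [stats::fisher.test], the sum-of-probabilities-at-most-
#' the-observed convention). P-values are Bonferroni-adjusted over all
#' taxa tested in the call; a taxon is assigned to the region where its
#' presence proportion is higher iff its adjusted p-value is at most
#' `alpha`.
#'
#' @param presence Logical matrix, samples x taxa (see [presence_filter]).
#' @param regions Named character vector: region per sample, exactly two
#'   distinct labels, each with at least one sample.
#' @param alpha Significance level (default 0.05).
#' @return A data.frame of class `fisher_association` with columns
#'   `taxon`, `present_<r1>`, `absent_<r1>`, `present_<r2>`,
#'   `absent_<r2>`, `p`, `p_adjusted`, `associated_region` (NA when not
#'   significant); attribute `family_size` records the Bonferroni family.
#' @export
fisher_association <- function(presence, regions, alpha = 0.05) {
  presence <- as.matrix(presence)
  regions <- regions[rownames(presence)]
  if (anyNA(regions)) stop("every sample needs a region label",
                           call. = FALSE)
  levs <- sort(unique(regions))
  if (length(levs) != 2L) {
    stop("exactly two region labels are required", call. = FALSE)
  }
  if (any(table(factor(regions, levels = levs)) == 0L)) {
    stop("each region must contain at least one sample", call. = FALSE)
  }
  m <- ncol(presence)
  res <- lapply(colnames(presence), function(taxon) {
    pres <- presence[, taxon]
    tab <- table(factor(pres, levels = c(TRUE, FALSE)),
                 factor(regions, levels = levs))
    p <- stats::fisher.test(tab)$p.value
    prop <- tab["TRUE", ] / colSums(tab)
    data.frame(taxon = taxon,
               present_1 = tab["TRUE", 1L], absent_1 = tab["FALSE", 1L],
               present_2 = tab["TRUE", 2L], absent_2 = tab["FALSE", 2L],
               p = p, prop_1 = prop[1L], prop_2 = prop[2L],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- pmin(1, res$p * m)
  res$associated_region <- ifelse(
    res$p_adjusted <= alpha,
    ifelse(res$prop_1 >= res$prop_2, levs[1L], levs[2L]),
    NA_character_)
  res$prop_1 <- res$prop_2 <- NULL
  names(res) <- c("taxon",
                  paste0(c("present_", "absent_"), levs[1L]),
                  paste0(c("present_", "absent_"), levs[2L]),
                  "p", "p_adjusted", "associated_region")
  rownames(res) <- NULL
  attr(res, "family_size") <- m
  attr(res, "regions") <- levs
  class(res) <- c("fisher_association", "data.frame")
  res
}

#' Patristic distance matrix of a phylogenetic tree
#'
#' `d(i, j)` is the sum of branch lengths on the path between leaves i
#' and j. The tree must carry a branch length on every edge.
#'
#' @param tree A newick string or an [ape::phylo] object.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = leaf
#'   labels.
#' @examples
#' patristic_matrix("((A:1,B:2):1,C:3);")
#' @export
patristic_matrix <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) {
    stop("tree must be a newick string or a phylo object", call. = FALSE)
  }
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    bad <- if (is.null(tree$edge.length)) 1L else
      which(is.na(tree$edge.length))[1L]
    stop(sprintf("missing branch length on edge %d (%d -> %d)", bad,
                 tree$edge[bad, 1L], tree$edge[bad, 2L]), call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("leaf labels must be unique", call. = FALSE)
  }
  ape::cophenetic.phylo(tree)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle entries, with a
#' one-sided (greater) permutation p-value: rows/columns of the second
#' matrix are permuted jointly and
#' `p = (1 + #\{r_perm >= r_obs\}) / (n_permutations + 1)`. Seeded and
#' reproducible; the caller's RNG state is left untouched.
#'
#' @param d1,d2 Distance matrices with identical label sets (order may
#'   differ; `d2` is aligned to `d1`).
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer seed.
#' @return An object of class `mantel_result`: list with `r`, `p`,
#'   `n_permutations`, `seed`.
#' @export
mantel_test <- function(d1, d2, n_permutations = 999L, seed = 1L) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  l1 <- rownames(d1); l2 <- rownames(d2)
  if (is.null(l1) || is.null(l2)) stop("matrices must have labels",
                                       call. = FALSE)
  if (!setequal(l1, l2)) {
    stop("label sets differ: ",
         paste(c(setdiff(l1, l2), setdiff(l2, l1)), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(n_permutations >= 1L)
  d2 <- d2[l1, l1]
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  r_obs <- stats::cor(v1, d2[lt])
  n <- nrow(d1)
  r_perm <- .with_seed(seed, vapply(seq_len(n_permutations), function(i) {
    p <- sample.int(n)
    stats::cor(v1, d2[p, p][lt])
  }, numeric(1L)))
  p <- (1 + sum(r_perm >= r_obs)) / (n_permutations + 1)
  structure(list(r = r_obs, p = p,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, p = %.4g (%d permutations, seed %d)\n",
              x$r, x$p, x$n_permutations, x$seed))
  invisible(x)
}

#' Drop leaves on unusually long pendant branches
#'
#' Removes leaves whose pendant branch length exceeds Q3 + k * IQR of all
#' pendant lengths. This operationalizes the removal of long-branch OTUs
#' before downstream phylogenetic statistics; k = 3 by default, a
#' deliberately permissive fence that only removes extreme outliers.
#'
#' @param tree A newick string or phylo object with branch lengths.
#' @param k IQR multiplier (default 3).
#' @return A phylo object; dropped leaf labels in attribute `dropped`.
#' @export
prune_long_branches <- function(tree, k = 3) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  n_tip <- length(tree$tip.label)
  pend <- tree$edge.length[match(seq_len(n_tip), tree$edge[, 2L])]
  q <- stats::quantile(pend, c(0.25, 0.75), names = FALSE)
  fence <- q[2L] + k * (q[2L] - q[1L])
  drop <- tree$tip.label[pend > fence]
  out <- if (length(drop)) ape::drop.tip(tree, drop) else tree
  attr(out, "dropped") <- drop
  out
}
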