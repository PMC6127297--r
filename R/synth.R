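# Seeded synthetic-data generators with planted ground truth. Every
# generator is a pure function of its parameters and seed and leaves the
# caller's RNG state untouched. Mutations are substitutions only, so
# anchored tail stacking is exact; indel-style variation is exercised via
# externally aligned inputs instead.

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.BASES <- c("A", "C", "G", "T")

# Random DNA with a given GC fraction.
.random_dna <- function(n, gc = 0.5) {
  paste(sample(.BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Substitute each position independently with probability `rate`, always
# to a different base.
.mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- .seq_chars(seq)
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Synthetic host family with a conserved amplicon 3'-tail
#'
#' Emulates a host (Scleractinia-like) reference set: every sequence is
#' forward primer + insert (mutated from a shared root at
#' `body_divergence`) + a conserved tail region (mutated at
#' `tail_divergence`) + the reverse-primer binding site. Degenerate primer
#' positions are resolved deterministically, so every record is
#' amplifiable at zero mismatches. The planted truth contains the root's
#' stacked 40-nt tail and, per candidate length, the blocking primer the
#' designer should recover (the reverse complement of the root window
#' under the overlap convention); candidates of different lengths share a
#' 5' prefix.
#'
#' @param n_host Number of sequences (default 50).
#' @param tail_divergence Per-base substitution probability in the
#'   conserved tail (default 0.02).
#' @param body_divergence Per-base substitution probability in the insert
#'   (default 0.10).
#' @param insert_len Insert length between the primer sites and the tail
#'   (default 250).
#' @param conserved_len Length of the conserved tail region upstream of
#'   the reverse-primer site (default 40).
#' @param primers [primer_set] targeted (default the published 18SV1V2
#'   set).
#' @param gc GC fraction of random sequence (default 0.4, matching the
#'   AT-rich character of 18S variable loops).
#' @param overlap_len,min_len,max_len Designer conventions used to compute
#'   the planted blockers (defaults 10, 20, 29).
#' @param seed Integer seed.
#' @return List with `db` (a [ref_db]), `primers`, and `truth`: list with
#'   `root_tail` (the root's 40-nt stacked tail), `blocker_by_length`
#'   (named character vector over `min_len:max_len`), and
#'   `blocker_full` (the `max_len` candidate; shorter planted blockers are
#'   its prefixes).
#' @export
synth_host_family <- function(n_host = 50L, tail_divergence = 0.02,
                              body_divergence = 0.10, insert_len = 250L,
                              conserved_len = 40L,
                              primers = scleractinia_primer_sets()[["18SV1V2"]],
                              gc = 0.4, overlap_len = 10L, min_len = 20L,
                              max_len = 29L, seed = 1L) {
  stopifnot(inherits(primers, "primer_set"))
  fwd <- .resolve_iupac(primers$forward)
  site <- .resolve_iupac(revcomp(primers$reverse))
  rev_len <- nchar(site)
  target_tm <- mean(c(melting_temperature(primers$forward),
                      melting_temperature(primers$reverse)))
  .with_seed(seed, {
    root_insert <- .random_dna(insert_len, gc)
    # Draw the conserved tail until the planted family admits at least
    # one Tm-compatible blocker, so the planted truth is designable by
    # construction (a real host tail that supports no Tm-matched blocker
    # would never have led to a blocking-primer study).
    root_cons <- NULL
    for (try in 1:100) {
      cand_cons <- .random_dna(conserved_len, gc)
      tail40 <- substr(paste0(cand_cons, site),
                       conserved_len + rev_len - 39L,
                       conserved_len + rev_len)
      tms <- vapply(seq(min_len, max_len), function(L) {
        cols <- .window_cols(40L, rev_len, L, overlap_len)
        melting_temperature(substr(tail40, cols[1L], cols[length(cols)]))
      }, numeric(1L))
      if (any(abs(tms - target_tm) <= 5)) { root_cons <- cand_cons; break }
    }
    if (is.null(root_cons)) {
      stop("could not draw a Tm-compatible conserved tail", call. = FALSE)
    }
    seqs <- vapply(seq_len(n_host), function(i) {
      paste0(fwd, .mutate(root_insert, body_divergence),
             .mutate(root_cons, tail_divergence), site)
    }, character(1L))
    ids <- sprintf("host_%03d", seq_len(n_host))
    tax <- rep(list(c("Eukaryota", "Opisthokonta", "Metazoa", "Cnidaria",
                      "Hexacorallia", "Scleractinia", "Pocilloporidae")),
               n_host)
    db <- ref_db(ids, seqs, tax, label = "synthetic-host")
    root_amp <- paste0(fwd, root_insert, root_cons, site)
    tail_len <- 40L
    root_tail <- substr(root_amp, nchar(root_amp) - tail_len + 1L,
                        nchar(root_amp))
    blockers <- vapply(seq(min_len, max_len), function(L) {
      cols <- .window_cols(tail_len, rev_len, L, overlap_len)
      revcomp(substr(root_tail, cols[1L], cols[length(cols)]))
    }, character(1L))
    names(blockers) <- as.character(seq(min_len, max_len))
    list(db = db, primers = primers,
         truth = list(root_tail = root_tail,
                      blocker_by_length = blockers,
                      blocker_full = unname(blockers[length(blockers)])))
  })
}

#' Synthetic off-target (exclusion-free) database with labeled groups
#'
#' Emulates a metazoa-free reference set: taxon groups of amplifiable
#' sequences whose tails descend from independent roots, optionally with a
#' planted fraction of "carrier" sequences bearing the host's conserved
#' tail (and therefore blocked by the host blocker). The planted truth
#' records the exact carrier count per group.
#'
#' @param group_sizes Named integer vector: sequences per taxon group
#'   (defaults mirror common off-target groups).
#' @param carrier_fraction Fraction of each group carrying the host tail;
#'   scalar or named vector per group (default 0).
#' @param host_tail Conserved host tail region (required when any carrier
#'   fraction is positive; use `truth$root_tail` trimmed of the primer
#'   site, or pass the family's conserved region).
#' @param divergence Within-group per-base substitution rate (default
#'   0.05).
#' @param insert_len,gc,primers,seed As in [synth_host_family].
#' @return List with `db` (a [ref_db]) and `truth`: data.frame with
#'   columns `group`, `n`, `n_carriers`.
#' @export
synth_offtarget_db <- function(group_sizes = c(Rhizaria = 40L,
                                               Alveolata = 40L,
                                               Nucletmycea = 30L,
                                               Cryptomonadales = 20L,
                                               Chloroplastida = 20L),
                               carrier_fraction = 0,
                               host_tail = NULL, divergence = 0.05,
                               insert_len = 250L,
                               primers = scleractinia_primer_sets()[["18SV1V2"]],
                               gc = 0.4, seed = 1L) {
  stopifnot(inherits(primers, "primer_set"))
  if (is.null(names(group_sizes))) {
    stop("group_sizes must be named by taxon group", call. = FALSE)
  }
  cf <- if (length(carrier_fraction) == 1L) {
    stats::setNames(rep(carrier_fraction, length(group_sizes)),
                    names(group_sizes))
  } else carrier_fraction[names(group_sizes)]
  if (any(cf > 0) && is.null(host_tail)) {
    stop("host_tail is required when carrier_fraction > 0", call. = FALSE)
  }
  fwd <- .resolve_iupac(primers$forward)
  site <- .resolve_iupac(revcomp(primers$reverse))
  .with_seed(seed, {
    ids <- character(0L); seqs <- character(0L); tax <- list()
    truth <- data.frame(group = names(group_sizes),
                        n = as.integer(group_sizes),
                        n_carriers = 0L, stringsAsFactors = FALSE)
    for (g in names(group_sizes)) {
      n <- group_sizes[[g]]
      n_car <- round(cf[[g]] * n)
      truth$n_carriers[truth$group == g] <- n_car
      root_insert <- .random_dna(insert_len, gc)
      root_tail <- .random_dna(40L, gc)
      for (i in seq_len(n)) {
        tail_i <- if (i <= n_car) host_tail else
          .mutate(root_tail, divergence)
        ids <- c(ids, sprintf("%s_%03d", tolower(g), i))
        seqs <- c(seqs, paste0(fwd, .mutate(root_insert, divergence),
                               tail_i, site))
        tax[[length(tax) + 1L]] <- c("Eukaryota", g,
                                     paste0(g, "_genus"))
      }
    }
    list(db = ref_db(ids, seqs, tax, label = "synthetic-offtarget"),
         truth = truth)
  })
}

#' Synthetic reference clade panel with controlled identities
#'
#' Builds aligned (gapless, equal-length) reference sequences for
#' `n_clades` clades plus planted query sequences, with tightly controlled
#' pairwise identities: every clade owns a disjoint block of signature
#' positions mutated away from a shared root, so between-clade identity is
#' exactly `1 - 2 * block / len`; within-clade variation re-mutates
#' positions inside the clade's own block, so it never disturbs
#' between-clade identity. Realized identities are within 1% of the
#' requested values. When `within_identity < between_identity` the
#' construction degenerates (member mutations are spread over the whole
#' sequence) and the clades become inseparable, as requested.
#'
#' @param n_clades Number of clades (default 5; labeled A, B, C, D, G as
#'   in Symbiodinium panels, then letters).
#' @param refs_per_clade References per clade (default 3).
#' @param n_queries Planted query sequences (default 5).
#' @param query_clades Clade per query (default: cycled over clades).
#' @param within_identity,between_identity Target pairwise identities
#'   (defaults 0.99 and 0.90).
#' @param alignment_len Alignment length (default 600).
#' @param seed Integer seed.
#' @return List with `ref_seqs`, `ref_clades` (named by reference id),
#'   `query_seqs`, and `truth` (named clade per query id).
#' @export
synth_reference_panel <- function(n_clades = 5L, refs_per_clade = 3L,
                                  n_queries = 5L, query_clades = NULL,
                                  within_identity = 0.99,
                                  between_identity = 0.90,
                                  alignment_len = 600L, seed = 1L) {
  stopifnot(n_clades >= 2L)
  labels <- if (n_clades <= 5L) c("A", "B", "C", "D", "G")[seq_len(n_clades)]
    else LETTERS[seq_len(n_clades)]
  L <- alignment_len
  m <- round((1 - between_identity) * L / 2)
  k <- round((1 - within_identity) * L / 2)
  if (n_clades * max(m, 1L) > L) {
    stop("alignment too short for the requested between-clade identity",
         call. = FALSE)
  }
  if (is.null(query_clades)) {
    query_clades <- rep(labels, length.out = n_queries)
  }
  .with_seed(seed, {
    root <- .seq_chars(.random_dna(L, 0.5))
    blocks <- split(seq_len(n_clades * m),
                    rep(seq_len(n_clades), each = m))
    clade_roots <- lapply(seq_len(n_clades), function(ci) {
      x <- root
      for (pos in blocks[[ci]]) {
        x[pos] <- sample(setdiff(.BASES, x[pos]), 1L)
      }
      x
    })
    names(clade_roots) <- labels
    # Degenerate request (between-clade identity above within-clade):
    # real clades cannot satisfy it, so drop the clade signatures
    # entirely and let member variation swamp any clade structure.
    inseparable <- between_identity > within_identity
    if (inseparable) clade_roots <- lapply(clade_roots, function(x) root)
    member <- function(clade) {
      x <- clade_roots[[clade]]
      pool <- blocks[[match(clade, labels)]]
      if (inseparable || k > length(pool)) pool <- seq_len(L)
      if (k > 0L) {
        for (pos in sample(pool, k)) {
          avoid <- unique(c(x[pos], root[pos]))
          x[pos] <- sample(setdiff(.BASES, avoid), 1L)
        }
      }
      paste(x, collapse = "")
    }
    ref_seqs <- character(0L); ref_clades <- character(0L)
    for (cl in labels) {
      for (i in seq_len(refs_per_clade)) {
        id <- sprintf("ref_%s_%d", cl, i)
        ref_seqs[id] <- member(cl)
        ref_clades[id] <- cl
      }
    }
    query_seqs <- character(0L); truth <- character(0L)
    for (i in seq_len(n_queries)) {
      id <- sprintf("otu_%03d", i)
      query_seqs[id] <- member(query_clades[i])
      truth[id] <- query_clades[i]
    }
    list(ref_seqs = ref_seqs, ref_clades = ref_clades,
         query_seqs = query_seqs, truth = truth)
  })
}

#' Synthetic OTU table with planted region associations
#'
#' Samples from two regions; associated taxa are present with probability
#' `assoc_effect[1]` in the first region and `assoc_effect[2]` in the
#' second, null taxa with probability `null_presence` everywhere. Where
#' present, counts are `min_reads` plus a Poisson draw, so the presence
#' rule at `min_reads` recovers the planted presence pattern exactly.
#'
#' @param n_samples_per_region Samples per region (default 8).
#' @param regions Two region labels (default c("DJ", "NC")).
#' @param n_assoc Number of region-associated taxa (default 3).
#' @param assoc_effect Presence probabilities (region 1, region 2) for
#'   associated taxa (default c(0.9, 0.1)).
#' @param n_null Number of null taxa (default 10).
#' @param null_presence Presence probability of null taxa (default 0.5).
#' @param min_reads Minimum count where present (default 3).
#' @param lambda Poisson mean of extra reads (default 20).
#' @param seed Integer seed.
#' @return List with `table` (an [otu_table_bp] with regions and a
#'   genus-bearing taxonomy) and `truth`: data.frame `taxon`,
#'   `associated` (logical), `favored_region`.
#' @export
synth_otu_table <- function(n_samples_per_region = 8L,
                            regions = c("DJ", "NC"), n_assoc = 3L,
                            assoc_effect = c(0.9, 0.1), n_null = 10L,
                            null_presence = 0.5, min_reads = 3L,
                            lambda = 20, seed = 1L) {
  stopifnot(length(regions) == 2L)
  .with_seed(seed, {
    samples <- c(sprintf("%s_%02d", regions[1L],
                         seq_len(n_samples_per_region)),
                 sprintf("%s_%02d", regions[2L],
                         seq_len(n_samples_per_region)))
    region_of <- stats::setNames(rep(regions,
                                     each = n_samples_per_region),
                                 samples)
    taxa <- c(if (n_assoc > 0L) sprintf("assoc_%02d", seq_len(n_assoc)),
              if (n_null > 0L) sprintf("null_%02d", seq_len(n_null)))
    counts <- matrix(0L, nrow = length(samples), ncol = length(taxa),
                     dimnames = list(samples, taxa))
    for (j in seq_along(taxa)) {
      p <- if (j <= n_assoc) {
        ifelse(region_of == regions[1L], assoc_effect[1L],
               assoc_effect[2L])
      } else rep(null_presence, length(samples))
      pres <- stats::runif(length(samples)) < p
      counts[pres, j] <- min_reads + stats::rpois(sum(pres), lambda)
    }
    tax <- lapply(taxa, function(t) c("Eukaryota", "Alveolata", t))
    truth <- data.frame(
      taxon = taxa,
      associated = seq_along(taxa) <= n_assoc,
      favored_region = ifelse(seq_along(taxa) <= n_assoc,
                              regions[which.max(assoc_effect)],
                              NA_character_),
      stringsAsFactors = FALSE)
    list(table = otu_table_bp(counts, region_of, tax), truth = truth)
  })
}

#' Random phylogenetic tree as a newick string
#'
#' Random topology with uniform branch lengths in (0.05, 1); seeded and
#' reproducible.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param seed Integer seed.
#' @return Newick string with branch lengths.
#' @export
synth_tree <- function(n_leaves, seed = 1L) {
  stopifnot(n_leaves >= 2L)
  .with_seed(seed, {
    tr <- ape::rtree(n_leaves, rooted = TRUE,
                     br = function(n) stats::runif(n, 0.05, 1))
    ape::write.tree(tr)
  })
}
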