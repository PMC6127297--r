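# Independent oracles used by the tests. These are deliberately naive
# (literal set expansion, exhaustive enumeration, brute-force
# agglomeration) and share no code with the package internals.

# Literal IUPAC expansion sets.
ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Mismatches by per-position any-pair-equal test over full expansions.
oracle_count_mismatches <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sum(vapply(seq_along(ca), function(i) {
    !any(ORACLE_SETS[[ca[i]]] %in% ORACLE_SETS[[cb[i]]])
  }, logical(1)))
}

# Naive agglomerative clustering: repeatedly merge the closest pair of
# clusters (by the linkage distance) while it is within the cutoff.
oracle_cluster <- function(idm, cutoff, linkage = "complete") {
  d <- 1 - idm
  clusters <- as.list(rownames(idm))
  repeat {
    if (length(clusters) == 1) break
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        link <- if (linkage == "complete") max(dd) else mean(dd)
        if (link < best_d) { best_d <- link; best <- c(i, j) }
      }
    }
    if (best_d > cutoff + 1e-12) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(nrow(idm))
  names(out) <- rownames(idm)
  for (k in seq_along(clusters)) out[clusters[[k]]] <- k
  out
}

# Partitions as label co-membership (cluster ids are arbitrary).
same_partition <- function(p1, p2) {
  p1 <- p1[sort(names(p1))]; p2 <- p2[sort(names(p2))]
  m1 <- outer(p1, p1, "=="); m2 <- outer(p2, p2, "==")
  all(m1 == m2)
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum of probabilities of all tables with the observed margins whose
# probability is at most the observed one (with the customary 1 + 1e-7
# relative slack for ties).
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact one-sided Mantel p by enumerating all label permutations.
oracle_mantel_exact <- function(d1, d2) {
  labs <- rownames(d1)
  d2 <- d2[labs, labs]
  lt <- lower.tri(d1)
  r_obs <- cor(d1[lt], d2[lt])
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rs <- vapply(perms(seq_along(labs)), function(p) {
    cor(d1[lt], d2[p, p][lt])
  }, numeric(1))
  mean(rs >= r_obs - 1e-12)
}

# Random IUPAC string with at most `max_degenerate` ambiguity codes.
random_iupac <- function(len, max_degenerate = 4) {
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  ndeg <- sample(0:min(max_degenerate, len), 1)
  if (ndeg > 0) {
    pos <- sample(len, ndeg)
    bases[pos] <- sample(c("R", "Y", "S", "W", "K", "M", "B", "D", "H",
                           "V", "N"), ndeg, replace = TRUE)
  }
  paste(bases, collapse = "")
}

write_fasta_lines <- function(lines, path = tempfile(fileext = ".fasta")) {
  writeLines(lines, path)
  path
}
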