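test_that("pairwise identity handles mismatches, gaps and overhangs", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1.0)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  expect_equal(pairwise_identity("--ACGT", "TTACGT"), 1.0)
  # internal gap in one sequence counts as mismatch
  expect_equal(pairwise_identity("AC-T", "ACGT"), 0.75)
  # column gapped in both is skipped
  expect_equal(pairwise_identity("AC-T", "AC-T"), 1.0)
  expect_error(pairwise_identity("ACG", "ACGT"), "equal length")
  expect_error(pairwise_identity("--AA", "TT--"), "overlap")
})

test_that("identity matrices are symmetric with unit diagonal", {
  pan <- synth_reference_panel(n_clades = 3, refs_per_clade = 2,
                               n_queries = 0, seed = 8)
  idm <- identity_matrix(pan$ref_seqs)
  expect_equal(idm, t(idm))
  expect_equal(unname(diag(idm)), rep(1, nrow(idm)))
  expect_true(all(idm >= 0 & idm <= 1))
})

test_that("threshold clustering matches hand-worked four-taxon cases", {
  idm <- matrix(0.90, 4, 4,
                dimnames = list(c("a1", "a2", "b1", "b2"),
                                c("a1", "a2", "b1", "b2")))
  diag(idm) <- 1
  idm["a1", "a2"] <- idm["a2", "a1"] <- 0.99
  idm["b1", "b2"] <- idm["b2", "b1"] <- 0.99
  p95 <- cluster_at(idm, 0.95)
  expect_equal(length(unique(p95)), 2L)
  expect_equal(p95[["a1"]], p95[["a2"]])
  expect_equal(p95[["b1"]], p95[["b2"]])
  expect_true(p95[["a1"]] != p95[["b1"]])
  expect_equal(length(unique(cluster_at(idm, 0.89))), 1L)
  # identical sequences cluster together at any threshold
  id2 <- matrix(1, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(length(unique(cluster_at(id2, 0.99))), 1L)
})

test_that("clustering agrees with a brute-force agglomerative oracle", {
  set.seed(19)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    labs <- paste0("s", seq_len(n))
    idm <- matrix(0, n, n, dimnames = list(labs, labs))
    vals <- runif(n * (n - 1) / 2, 0.6, 1)
    idm[lower.tri(idm)] <- vals
    idm <- idm + t(idm)
    diag(idm) <- 1
    t0 <- runif(1, 0.7, 0.99)
    mine <- cluster_at(idm, t0)
    ref <- oracle_cluster(idm, 1 - t0)
    expect_true(same_partition(mine, ref))
  }
})

test_that("partitions at higher thresholds refine lower-threshold partitions", {
  pan <- synth_reference_panel(seed = 12)
  idm <- identity_matrix(pan$ref_seqs)
  prev <- NULL
  for (t in seq(0.90, 0.99, by = 0.01)) {
    part <- cluster_at(idm, t)
    if (!is.null(prev)) {
      # every cluster at threshold t is inside one cluster at t - 0.01
      joined <- tapply(prev[names(part)], part, function(v)
        length(unique(v)))
      expect_true(all(joined == 1))
    }
    prev <- part
  }
})

test_that("the separation threshold scan finds the lowest separating cutoff", {
  pan <- synth_reference_panel(within_identity = 0.99,
                               between_identity = 0.90, seed = 14)
  idm <- identity_matrix(pan$ref_seqs)
  expect_equal(find_separation_threshold(idm, pan$ref_clades), 0.91)
  expect_equal(find_separation_threshold(idm, pan$ref_clades,
                                         pick = "highest"), 0.99)
  expect_error(find_separation_threshold(idm,
                                         setNames(rep("A", nrow(idm)),
                                                  rownames(idm))),
               "two clades")
})

test_that("inseparable panels (between > within identity) yield failure", {
  pan <- synth_reference_panel(within_identity = 0.99,
                               between_identity = 0.995, seed = 15)
  idm <- identity_matrix(pan$ref_seqs)
  expect_warning(t0 <- find_separation_threshold(idm, pan$ref_clades),
                 "no scanned threshold")
  expect_true(is.na(t0))
})

test_that("co-clustering annotation recovers planted clade labels", {
  pan <- synth_reference_panel(n_queries = 10, seed = 16)
  ann <- annotate_by_cocluster(pan$query_seqs, pan$ref_seqs,
                               pan$ref_clades, threshold = 0.91)
  expect_equal(setNames(ann$clade, ann$otu_id), pan$truth)
})

test_that("distant queries and missing references give 'unassigned'", {
  pan <- synth_reference_panel(n_queries = 0, seed = 17)
  far <- setNames(paste(rep("A", nchar(pan$ref_seqs[1])), collapse = ""),
                  "otu_far")
  ann <- annotate_by_cocluster(far, pan$ref_seqs, pan$ref_clades, 0.91)
  expect_equal(ann$clade, "unassigned")
  expect_warning(
    ann0 <- annotate_by_cocluster(far, character(0), character(0), 0.91),
    "no reference")
  expect_equal(ann0$clade, "unassigned")
})

test_that("an OTU identical to a reference inherits its clade", {
  pan <- synth_reference_panel(n_queries = 0, seed = 18)
  q <- setNames(pan$ref_seqs[["ref_C_1"]], "otu_c")
  ann <- annotate_by_cocluster(q, pan$ref_seqs, pan$ref_clades, 0.91)
  expect_equal(ann$clade, "C")
})
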