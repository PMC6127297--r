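make_table <- function() {
  counts <- matrix(c(5, 0, 3,
                     7, 2, 0,
                     1, 4, 9), nrow = 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"),
                                   c("otu1", "otu2", "otu3")))
  otu_table_bp(counts,
               regions = c(s1 = "DJ", s2 = "DJ", s3 = "NC"),
               taxonomy = list(c("Eukaryota", "Ciliophora", "Licnophora"),
                               c("Eukaryota", "Ciliophora", "Licnophora"),
                               c("Eukaryota", "Apicomplexa", "Coccidia")),
               coverage = c(0.95, 0.90, 0.89))
}

test_that("coverage filtering is inclusive at the threshold", {
  tab <- make_table()
  kept <- filter_coverage(tab)
  expect_equal(colnames(kept$counts), c("otu1", "otu2"))
  expect_equal(ncol(filter_coverage(tab, 0)$counts), 3L)
  expect_warning(empty <- filter_coverage(tab, 0.99), "no OTU")
  expect_equal(ncol(empty$counts), 0L)
  tab$coverage <- NULL
  expect_error(filter_coverage(tab), "no coverage")
})

test_that("presence requires the minimum read count", {
  counts <- matrix(0:4, nrow = 1,
                   dimnames = list("s", paste0("o", 1:5)))
  expect_equal(unname(presence_filter(counts)[1, ]),
               c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(unname(presence_filter(counts, 1)[1, ]), 0:4 > 0)
  zero <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_false(any(presence_filter(zero)))
})

test_that("genus aggregation sums counts and truncates taxonomy", {
  tab <- make_table()
  agg <- aggregate_genus(tab)
  expect_equal(colnames(agg$counts), c("Licnophora", "Coccidia"))
  expect_equal(unname(agg$counts["s1", "Licnophora"]), 5)
  expect_equal(unname(agg$counts["s2", "Licnophora"]), 9)  # 7 + 2
  expect_equal(agg$taxonomy[[1]],
               c("Eukaryota", "Ciliophora", "Licnophora"))
  # all-distinct genera leave the table unchanged up to relabeling
  tab2 <- tab
  tab2$taxonomy[[2]] <- c("Eukaryota", "Ciliophora", "Zoothamnopsis")
  agg2 <- aggregate_genus(tab2)
  expect_equal(unname(agg2$counts), unname(tab2$counts))
  # missing genus falls into the unclassified bucket
  tab3 <- tab
  tab3$taxonomy[[3]] <- character(0)
  expect_true("unclassified" %in% colnames(aggregate_genus(tab3)$counts))
})

test_that("Pielou evenness matches analytic values and vegan", {
  expect_equal(pielou_evenness(c(10, 10, 10, 10)), 1.0)
  expect_equal(pielou_evenness(c(2, 1, 1)), 0.9464, tolerance = 1e-4)
  expect_equal(pielou_evenness(c(1000, 1, 1)), 0.01436898,
               tolerance = 1e-5)
  # scale invariance
  set.seed(6)
  x <- rpois(20, 30) + 1
  expect_equal(pielou_evenness(x), pielou_evenness(17.3 * x))
  expect_error(pielou_evenness(c(5, 0, 0)), "fewer than 2")
  skip_if_not_installed("vegan")
  expect_equal(pielou_evenness(x),
               vegan::diversity(x) / log(sum(x > 0)))
})

test_that("Fisher association reproduces the worked hypergeometric case", {
  presence <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                     ncol = 1, dimnames = list(paste0("s", 1:6), "taxon"))
  regions <- setNames(rep(c("DJ", "NC"), each = 3), paste0("s", 1:6))
  res <- fisher_association(presence, regions)
  expect_equal(res$p, 0.1)  # 2 * C(3,3) C(3,0) / C(6,3)
  # equal presence proportions give p = 1
  pres2 <- matrix(c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
                  ncol = 1, dimnames = list(paste0("s", 1:6), "t"))
  expect_equal(fisher_association(pres2, regions)$p, 1.0)
})

test_that("Bonferroni adjustment multiplies by the family size and caps at 1", {
  tab <- synth_otu_table(n_assoc = 2, n_null = 3, seed = 5)
  pres <- presence_filter(tab$table)
  res <- fisher_association(pres, tab$table$regions)
  expect_equal(attr(res, "family_size"), 5L)
  expect_equal(res$p_adjusted, pmin(1, res$p * 5))
  expect_true(all(res$p <= res$p_adjusted))
})

test_that("significant taxa are assigned to the region with higher presence", {
  tab <- synth_otu_table(n_samples_per_region = 6, n_assoc = 1,
                         assoc_effect = c(1, 0), n_null = 0, seed = 7)
  pres <- presence_filter(tab$table)
  res <- fisher_association(pres, tab$table$regions)
  expect_equal(res$associated_region, "DJ")
  expect_error(fisher_association(pres[1:6, , drop = FALSE],
                                  tab$table$regions[1:6]),
               "two region")
})

test_that("patristic distances are path sums of branch lengths", {
  m <- patristic_matrix("((A:1,B:2):1,C:3);")
  expect_equal(m["A", "B"], 3)
  expect_equal(m["A", "C"], 5)
  expect_equal(m["B", "C"], 6)
  expect_equal(unname(diag(m)), rep(0, 3))
  star <- patristic_matrix("(A:1,B:1,C:1,D:1);")
  expect_true(all(star[upper.tri(star)] == 2))
  expect_error(patristic_matrix("((A:1,B:2):1,C);"), "branch length")
})

test_that("patristic matrices of additive trees satisfy the four-point condition", {
  for (s in 1:5) {
    m <- patristic_matrix(synth_tree(6, seed = s))
    labs <- rownames(m)
    combs <- combn(labs, 4)
    for (j in seq_len(ncol(combs))) {
      q <- combs[, j]
      sums <- c(m[q[1], q[2]] + m[q[3], q[4]],
                m[q[1], q[3]] + m[q[2], q[4]],
                m[q[1], q[4]] + m[q[2], q[3]])
      two_largest <- sort(sums, decreasing = TRUE)[1:2]
      expect_equal(two_largest[1], two_largest[2], tolerance = 1e-8)
    }
  }
})

test_that("Mantel self-comparison gives r = 1 with the minimal p", {
  m <- patristic_matrix(synth_tree(7, seed = 3))
  res <- mantel_test(m, m, n_permutations = 199, seed = 11)
  expect_equal(res$r, 1.0)
  expect_equal(res$p, 1 / 200)
  # positive affine transforms leave r at 1
  res2 <- mantel_test(m, 2.5 * m + 0.3 * (1 - diag(nrow(m))),
                      n_permutations = 99, seed = 11)
  expect_equal(res2$r, 1.0)
})

test_that("Mantel is symmetric, seeded, and label-checked", {
  m1 <- patristic_matrix(synth_tree(6, seed = 21))
  m2 <- patristic_matrix(synth_tree(6, seed = 22))
  rownames(m2) <- colnames(m2) <- rownames(m1)
  a <- mantel_test(m1, m2, 499, seed = 9)
  b <- mantel_test(m2, m1, 499, seed = 9)
  expect_equal(a$r, b$r)
  expect_equal(a$p, mantel_test(m1, m2, 499, seed = 9)$p)
  m3 <- m2
  rownames(m3) <- colnames(m3) <- paste0("other", 1:6)
  expect_error(mantel_test(m1, m3), "label sets differ")
})

test_that("permutation p converges to the exact enumeration for small n", {
  m1 <- patristic_matrix(synth_tree(5, seed = 31))
  m2 <- patristic_matrix(synth_tree(5, seed = 32))
  rownames(m2) <- colnames(m2) <- rownames(m1)
  exact <- oracle_mantel_exact(m1, m2)
  res <- mantel_test(m1, m2, n_permutations = 9999, seed = 13)
  se <- sqrt(exact * (1 - exact) / 9999)
  expect_lt(abs(res$p - exact), 3 * se + 2 / 10000)
})

test_that("Mantel r agrees with vegan", {
  skip_if_not_installed("vegan")
  m1 <- patristic_matrix(synth_tree(8, seed = 41))
  m2 <- patristic_matrix(synth_tree(8, seed = 42))
  rownames(m2) <- colnames(m2) <- rownames(m1)
  ref <- vegan::mantel(as.dist(m1), as.dist(m2), permutations = 99)
  expect_equal(mantel_test(m1, m2, 99, seed = 1)$r,
               unname(ref$statistic))
})

test_that("long pendant branches are pruned by the IQR fence", {
  tree <- ape::read.tree(text =
    "((A:0.1,B:0.1):0.1,((C:0.1,D:0.1):0.1,E:5):0.1);")
  pruned <- prune_long_branches(tree)
  expect_equal(attr(pruned, "dropped"), "E")
  expect_setequal(pruned$tip.label, c("A", "B", "C", "D"))
})
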