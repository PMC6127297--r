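fam0 <- synth_host_family(n_host = 10, tail_divergence = 0, seed = 41)
blocker0 <- unname(fam0$truth$blocker_by_length[["25"]])

test_that("a planted host record is blocked by the planted blocker", {
  rec <- fam0$db[1]
  expect_true(is_blocked(rec, fam0$primers, blocker0))
})

test_that("one substitution in the blocker window flips the call at budget 0", {
  rec <- list(id = fam0$db$ids[1], seq = fam0$db$seqs[1])
  hit <- extract_amplicon(rec, fam0$primers)
  # mutate a window position 5' of the reverse-primer site
  pos <- hit$rev_site_start - 3L
  old <- substr(rec$seq, pos, pos)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  mut <- rec
  substr(mut$seq, pos, pos) <- new
  expect_false(is_blocked(mut, fam0$primers, blocker0))
  expect_true(is_blocked(mut, fam0$primers, blocker0,
                         blocking_criteria(max_mismatch = 1)))
})

test_that("non-amplifiable records are never blocked", {
  rec <- list(id = "na", seq = strrep("AT", 100))
  expect_false(is_blocked(rec, fam0$primers, blocker0))
})

test_that("a blocker shorter than the overlap contract errors", {
  expect_error(is_blocked(fam0$db[1], fam0$primers, "ACGTACGT"),
               "overlap contract")
})

test_that("report fractions equal planted blocked counts exactly", {
  off <- synth_offtarget_db(
    group_sizes = c(Rhizaria = 50, Alveolata = 40, Nucletmycea = 30),
    carrier_fraction = c(Rhizaria = 0.02, Alveolata = 0, Nucletmycea = 0.1),
    host_tail = substr(fam0$truth$root_tail, 1, 22),
    seed = 42)
  # carriers carry the host's conserved tail region upstream of the site
  rep <- specificity_report(blocker0, fam0$primers, fam0$db, off$db,
                            host_label = "Scleractinia")
  expect_equal(rep$group[1], "Scleractinia")
  expect_equal(rep$fraction_blocked[1], 1.0)
  for (g in off$truth$group) {
    row <- rep[rep$group == g, ]
    want <- off$truth[off$truth$group == g, ]
    expect_equal(row$n_total, want$n)
    expect_equal(row$n_blocked, want$n_carriers)
  }
  expect_equal(sum(rep$n_total[-1]), sum(off$truth$n))
  # rows sorted by blocked fraction, descending
  expect_equal(rep$fraction_blocked, sort(rep$fraction_blocked,
                                          decreasing = TRUE))
})

test_that("random off-target sequences are essentially never blocked", {
  off <- synth_offtarget_db(group_sizes = c(Rhizaria = 50), seed = 43)
  counts <- blockprimr:::.blocked_counts(off$db, fam0$primers, blocker0,
                                         blocking_criteria())
  expect_equal(counts$n_blocked, 0L)
})

test_that("blocked fractions are monotone in the mismatch budget", {
  fam <- synth_host_family(n_host = 20, tail_divergence = 0.05, seed = 44)
  fracs <- vapply(0:3, function(mm) {
    s <- blockprimr:::.blocked_counts(
      fam$db, fam$primers, unname(fam$truth$blocker_by_length[["25"]]),
      blocking_criteria(max_mismatch = mm))
    s$n_blocked / s$n_total
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("a 15/16 host case reports fraction 0.9375", {
  fam <- synth_host_family(n_host = 16, tail_divergence = 0, seed = 45)
  blocker <- unname(fam$truth$blocker_by_length[["25"]])
  db <- fam$db
  hit <- extract_amplicon(db[1], fam$primers)
  pos <- hit$rev_site_start - 5L
  old <- substr(db$seqs[1], pos, pos)
  substr(db$seqs[1], pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  rep <- specificity_report(blocker, fam$primers, db,
                            synth_offtarget_db(group_sizes =
                                                 c(Rhizaria = 5),
                                               seed = 46)$db)
  host_row <- rep[rep$n_total == 16, ]
  expect_equal(host_row$n_blocked, 15L)
  expect_equal(host_row$fraction_blocked, 15 / 16)
})

test_that("mixed-rank grouping via an explicit label map is honored", {
  off <- synth_offtarget_db(group_sizes = c(Rhizaria = 6, Alveolata = 4),
                            seed = 47)
  map <- c(Rhizaria = "SAR", Alveolata = "SAR")
  rep <- specificity_report(blocker0, fam0$primers, fam0$db, off$db,
                            group_map = map)
  expect_true("SAR" %in% rep$group)
  expect_equal(rep$n_total[rep$group == "SAR"], 10L)
})
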