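v1v2 <- scleractinia_primer_sets()[["18SV1V2"]]

test_that("melting temperature follows Wallace / GC-content formulas", {
  expect_equal(melting_temperature("AAAATTTTGGCC"), 32)
  expect_equal(melting_temperature("ACCTGGTTGATCCTGCCA"),
               64.9 + 41 * (10 - 16.4) / 18)
  # degenerate weighting: R counts half toward GC
  expect_equal(melting_temperature(strrep("R", 14)),
               64.9 + 41 * (7 - 16.4) / 14)
  set.seed(3)
  for (i in 1:20) {
    s <- random_iupac(sample(10:30, 1), max_degenerate = 6)
    expect_equal(melting_temperature(s), melting_temperature(revcomp(s)))
  }
  expect_error(melting_temperature("ACGTACGT"), "length")
})

test_that("tail stacking takes the final bases and drops short amplicons", {
  amps <- c(a = paste0(strrep("A", 96), "CCGG"),
            b = strrep("ACGT", 25),
            short = strrep("A", 39))
  expect_message(stack <- extract_tail_stack(amps, tail_len = 40),
                 "1 amplicon\\(s\\) shorter")
  expect_equal(length(stack$rows), 2L)
  expect_equal(unname(substr(stack$rows["a"], 37, 40)), "CCGG")
  expect_error(extract_tail_stack(character(0)), "no amplicons")
})

test_that("identical rows give frequency-1 columns and zero entropy", {
  stack <- tail_stack_from_rows(c(x = "ACGT", y = "ACGT", z = "ACGT"))
  expect_true(all(apply(stack$freqs, 2, max) == 1))
  expect_equal(column_entropy(stack)$H, rep(0, 4))
})

test_that("column entropy reproduces analytic values and stays in [0, 2]", {
  stack <- tail_stack_from_rows(c(a = "AAAN", b = "ACCN", c = "ACGN",
                                  d = "ACTN"))
  H <- column_entropy(stack)$H
  expect_equal(H[1], 0)                       # monomorphic
  expect_equal(H[2], -sum(c(.25, .75) * log2(c(.25, .75))))
  expect_equal(H[3], 2)                       # uniform over 4 bases
  expect_true(is.na(H[4]))                    # no unambiguous symbol
  two <- tail_stack_from_rows(c(a = "AA", b = "CA"))
  expect_equal(column_entropy(two)$H, c(1, 0))  # 50/50 column = 1 bit
  fr <- tail_stack_from_rows(c(a = "A", b = "A", c = "C", d = "G"))
  expect_equal(column_entropy(fr)$H, 1.5)       # (1/2, 1/4, 1/4, 0)
  set.seed(17)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    rows <- vapply(seq_len(n), function(j)
      paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
            collapse = ""), character(1))
    names(rows) <- paste0("r", seq_len(n))
    H <- column_entropy(tail_stack_from_rows(rows))$H
    expect_true(all(H >= 0 & H <= 2))
    mono <- apply(do.call(rbind, strsplit(rows, "")), 2,
                  function(col) length(unique(col)) == 1)
    expect_equal(H == 0, mono)
  }
})

test_that("anchored stacking equals gapless alignment for equal-length tails", {
  set.seed(2)
  amps <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
          collapse = ""), character(1))
  names(amps) <- paste0("s", 1:5)
  stack <- extract_tail_stack(amps, tail_len = 40)
  aligned <- substr(amps, 21, 60)  # a gapless alignment of the tails
  expect_equal(unname(stack$rows), unname(aligned))
})

test_that("candidate enumeration recovers an invariant planted tail exactly", {
  fam <- synth_host_family(n_host = 10, tail_divergence = 0,
                           body_divergence = 0, seed = 21)
  amps <- extract_amplicons(fam$db, fam$primers)
  stack <- extract_tail_stack(amps, primerset_name = fam$primers$name)
  cands <- enumerate_candidates(stack, fam$primers)
  expect_gt(nrow(cands), 0)
  for (i in seq_len(nrow(cands))) {
    L <- cands$length[i]
    expect_equal(cands$seq[i],
                 unname(fam$truth$blocker_by_length[[as.character(L)]]))
    # overlap contract: 5' prefix compatible with the reverse 3' end
    rp <- fam$primers$reverse
    expect_equal(count_mismatches(substr(cands$seq[i], 1, 10),
                                  substr(rp, nchar(rp) - 9, nchar(rp))),
                 0L)
    expect_lt(L, 30)
  }
})

test_that("a fully polymorphic stack yields no candidate (all-N guard)", {
  rows <- c(a = strrep("A", 40), b = strrep("C", 40), c = strrep("G", 40),
            d = strrep("T", 40))
  stack <- tail_stack_from_rows(rows)
  cands <- enumerate_candidates(stack, v1v2)
  expect_equal(nrow(cands), 0L)
})

test_that("enumeration errors when the stack cannot hold the window", {
  stack <- tail_stack_from_rows(c(a = strrep("A", 20), b = strrep("A", 20)))
  expect_error(enumerate_candidates(stack, v1v2), "too short")
  expect_error(enumerate_candidates(tail_stack_from_rows(
    c(a = strrep("A", 40))), v1v2, max_len = 35), "allow_long")
})

test_that("ranking is lexicographic with shorter length breaking ties", {
  fam <- synth_host_family(n_host = 12, tail_divergence = 0, seed = 33)
  off <- synth_offtarget_db(group_sizes = c(Rhizaria = 8), seed = 34)
  d <- design_blocking_primers(fam$db, off$db, fam$primers)
  cands <- d$candidates
  # with an invariant tail every candidate blocks all hosts and no
  # off-target record, so ties resolve to the shortest candidate first
  expect_true(all(cands$host_blocked == 1))
  expect_true(all(cands$offtarget_blocked == 0))
  expect_equal(cands$length, sort(cands$length))
  expect_equal(d$best$length, min(cands$length))
  # a worse host blocker never outranks a better one
  expect_true(all(diff(cands$host_blocked) <= 0))
  expect_error(rank_candidates(cands[0, ], fam$primers, fam$db, off$db),
               "no candidates")
})
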