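test_that("find_insertions detects planted candidate-specific runs", {
  # identity: no insertions
  aln <- c(candidate = "ACDEFGHIKL", ref1 = "ACDEFGHIKL",
           ref2 = "ACDEFGHIKL")
  expect_equal(nrow(find_insertions(aln, "candidate")), 0)

  # one 4-column insertion after reference position 5
  aln <- c(candidate = "ACDEFWWWWGHIKL",
           ref1 = "ACDEF----GHIKL",
           ref2 = "ACDEF----GHIKL")
  ins <- find_insertions(aln, "candidate")
  expect_equal(nrow(ins), 1)
  expect_equal(ins$col_start, 6)
  expect_equal(ins$col_end, 9)
  expect_equal(ins$ref_anchor, 5)

  # two separated runs, sorted
  aln <- c(candidate = "ACWWDEFGWWWHIKL",
           ref1 = "AC--DEFG---HIKL",
           ref2 = "AC--DEFG---HIKL")
  ins <- find_insertions(aln, "candidate")
  expect_equal(nrow(ins), 2)
  expect_true(all(diff(ins$col_start) > 0))
  expect_equal(ins$length, c(2, 3))

  expect_error(find_insertions(aln, "nope"), "not found")
})

test_that("gap_frac controls which columns count as insertions", {
  # only 1 of 2 references gapped: below the 0.8 default, above 0.5
  aln <- c(candidate = "ACDEFWWGHIKL",
           ref1 = "ACDEF--GHIKL",
           ref2 = "ACDEFMMGHIKL")
  expect_equal(nrow(find_insertions(aln, "candidate", gap_frac = 0.8)), 0)
  expect_equal(nrow(find_insertions(aln, "candidate", gap_frac = 0.5)), 1)
})

test_that("scan_stops reproduces the three published verdict patterns", {
  # intact candidate
  f0 <- simulate_pseudogene_fixture(seed = 61)
  r0 <- scan_stops(f0$aln, "candidate", f0$domain_span, f0$conserved_span,
                   nt_seq = f0$nt_seq)
  expect_identical(r0$verdict, "intact")
  expect_equal(r0$n_stops_total, 0)

  # stops only inside insertions
  f1 <- simulate_pseudogene_fixture(
    insertions = list(c(anchor = 40, len = 15, stops = 3),
                      c(anchor = 70, len = 8, stops = 2)),
    seed = 62)
  r1 <- scan_stops(f1$aln, "candidate", f1$domain_span, f1$conserved_span,
                   nt_seq = f1$nt_seq)
  expect_identical(r1$verdict, "pseudogene_insertion_only")
  expect_equal(r1$n_stops_total, 5)
  expect_equal(r1$n_stops_in_insertions, 5)
  expect_equal(r1$n_stops_outside_insertions, 0)
  expect_equal(nrow(r1$insertion_segments), 2)

  # a stop in the conserved span outside insertions
  f2 <- simulate_pseudogene_fixture(
    insertions = list(c(anchor = 40, len = 12, stops = 2)),
    stops_outside = 60, seed = 63)
  r2 <- scan_stops(f2$aln, "candidate", f2$domain_span, f2$conserved_span,
                   nt_seq = f2$nt_seq)
  expect_identical(r2$verdict, "pseudogene_conserved_disrupted")
  expect_equal(r2$n_stops_total, 3)
  expect_equal(r2$n_stops_outside_insertions, 1)
  expect_gte(r2$n_stops_in_conserved, 1)
})

test_that("stop counts satisfy in + out == total on random fixtures", {
  set.seed(64)
  for (i in 1:10) {
    n_ins <- sample(0:3, 1)
    anchors <- sort(sample(seq(15, 95, by = 5), n_ins))
    ins <- lapply(anchors, function(a) {
      c(anchor = a, len = sample(4:15, 1), stops = sample(0:3, 1))
    })
    outs <- sample(10:100, sample(0:3, 1))
    f <- simulate_pseudogene_fixture(insertions = ins,
                                     stops_outside = outs,
                                     seed = 640 + i)
    r <- scan_stops(f$aln, "candidate", f$domain_span, f$conserved_span,
                    nt_seq = f$nt_seq)
    expect_equal(r$n_stops_in_insertions + r$n_stops_outside_insertions,
                 r$n_stops_total)
    expect_equal(r$n_stops_total, f$truth$n_stops_total)
    expect_equal(r$n_stops_in_insertions, f$truth$n_stops_in_insertions)
    expect_identical(r$verdict, f$truth$verdict)
  }
})

test_that("removing an insertion segment only moves stops outward", {
  f <- simulate_pseudogene_fixture(
    insertions = list(c(anchor = 40, len = 12, stops = 3)),
    stops_outside = 80, seed = 65)
  full <- scan_stops(f$aln, "candidate", f$domain_span, f$conserved_span)
  none <- scan_stops(f$aln, "candidate", f$domain_span, f$conserved_span,
                     insertions = full$insertion_segments[0, ])
  expect_equal(none$n_stops_total, full$n_stops_total)
  expect_equal(none$n_stops_in_insertions, 0)
  expect_equal(none$n_stops_outside_insertions, full$n_stops_total)
})

test_that("nt_seq validation catches frame mismatches", {
  f <- simulate_pseudogene_fixture(seed = 66)
  bad <- paste0("A", f$nt_seq)  # frame shift
  expect_error(
    scan_stops(f$aln, "candidate", f$domain_span, nt_seq = bad),
    "does not match")
  # and the genuine sequence passes
  expect_s3_class(
    scan_stops(f$aln, "candidate", f$domain_span, nt_seq = f$nt_seq),
    "pseudogene_report")
})

test_that("stops outside the domain span are ignored", {
  f <- simulate_pseudogene_fixture(stops_outside = c(3, 105), seed = 67)
  # both planted stops fall outside the default domain span [10, 100]
  r <- scan_stops(f$aln, "candidate", f$domain_span, f$conserved_span)
  expect_equal(r$n_stops_total, 0)
  expect_identical(r$verdict, "intact")
})
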