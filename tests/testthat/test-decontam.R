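best_row <- function(q, e, bits = 100, pid = 90) {
  data.frame(query_id = q, subject_id = "s", pct_identity = pid,
             aln_len = 100L, mismatches = 0L, gap_opens = 0L,
             q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
             e_value = e, bit_score = bits, stringsAsFactors = FALSE)
}

na_row <- function(q) {
  r <- best_row(q, NA_real_, NA_real_, NA_real_)
  r$subject_id <- NA_character_
  r
}

test_that("host_filter applies both strict inequalities", {
  b <- rbind(best_row("q1", 1e-80, pid = 90),    # both conditions -> exclude
             best_row("q2", 1e-200, pid = 85),   # 85 is not > 85 -> keep
             best_row("q3", 1e-75, pid = 99),    # 1e-75 is not < 1e-75 -> keep
             best_row("q4", 1e-74, pid = 99),    # e-value too large -> keep
             na_row("q5"))                       # no hit -> keep
  d <- host_filter(b)
  expect_identical(d$decision, c("exclude", "keep", "keep", "keep", "keep"))
})

test_that("classify_contigs reproduces hand-evaluated fold-rule cases", {
  t_best <- rbind(best_row("a", 1e-100, 300), best_row("b", 1e-50, 100),
                  best_row("c", 1e-60, 200), best_row("d", 1e-52, 150),
                  na_row("e"), best_row("f", 1e-30, 90), na_row("g"))
  c_best <- rbind(best_row("a", 1e-50, 100), best_row("b", 1e-50, 100),
                  best_row("c", 1e-58, 190), best_row("d", 1e-50, 100),
                  best_row("e", 1e-20, 80), na_row("f"), na_row("g"))
  cls <- classify_contigs(t_best, c_best)
  lab <- setNames(cls$label, cls$query_id)
  expect_identical(lab[["a"]], "target")       # 1e-100 <= 1e-52, 300 >= 150
  expect_identical(lab[["b"]], "not_clear")    # identical best hits
  expect_identical(lab[["c"]], "not_clear")    # neither fold met
  expect_identical(lab[["d"]], "target")       # boundary: exactly 100x / 1.5x
  expect_identical(lab[["e"]], "contamination")  # single-db evidence
  expect_identical(lab[["f"]], "target")         # single-db evidence
  expect_identical(lab[["g"]], "not_clear")      # no hits at all
  rule <- setNames(cls$rule, cls$query_id)
  expect_identical(rule[["g"]], "no_hits")
  expect_identical(rule[["e"]], "single_db_contamination")
})

test_that("zero e-values are floored, keeping zero as strongest evidence", {
  t_best <- best_row("z", 0, 500)
  c_best <- best_row("z", 1e-150, 200)
  cls <- classify_contigs(t_best, c_best)
  expect_identical(cls$label, "target")
  # both zero: floored equal, not_clear
  cls2 <- classify_contigs(best_row("z", 0, 500), best_row("z", 0, 500))
  expect_identical(cls2$label, "not_clear")
})

test_that("swapping databases mirrors target and contamination labels", {
  set.seed(21)
  n <- 200
  t_best <- best_row(paste0("q", 1:n), 10^runif(n, -120, -5),
                     runif(n, 50, 400))
  c_best <- best_row(paste0("q", 1:n), 10^runif(n, -120, -5),
                     runif(n, 50, 400))
  a <- classify_contigs(t_best, c_best)
  b <- classify_contigs(c_best, t_best)
  swap <- c(target = "contamination", contamination = "target",
            not_clear = "not_clear")
  expect_identical(unname(swap[a$label]), b$label)
})

test_that("raising fold thresholds only moves labels toward not_clear", {
  set.seed(22)
  n <- 300
  t_best <- best_row(paste0("q", 1:n), 10^runif(n, -120, -5),
                     runif(n, 50, 400))
  c_best <- best_row(paste0("q", 1:n), 10^runif(n, -120, -5),
                     runif(n, 50, 400))
  lo <- classify_contigs(t_best, c_best, evalue_fold = 100,
                         bitscore_fold = 1.5)
  hi <- classify_contigs(t_best, c_best, evalue_fold = 1e4,
                         bitscore_fold = 3)
  moved <- lo$label != hi$label
  expect_true(all(hi$label[moved] == "not_clear"))
})

test_that("gc_partition routes by cutoff with inclusive low side", {
  expect_identical(gc_partition(c(0.35, 0.55, 0.3903), 0.3903),
                   c("target", "contamination", "target"))
  expect_warning(out <- gc_partition(c(0.2, NA), 0.39),
                 "undefined GC")
  expect_identical(out, c("target", "contamination"))
})

test_that("estimate_gc_cutoff finds the valley of a bimodal mixture", {
  set.seed(101)
  gc <- c(rnorm(500, 0.28, 0.03), rnorm(500, 0.55, 0.04))
  cut <- estimate_gc_cutoff(gc)
  expect_gt(cut, 0.35)
  expect_lt(cut, 0.48)
  expect_identical(attr(cut, "method"), "kde_valley")

  # brute-force misclassification-minimizing threshold agrees
  truth <- rep(c("lo", "hi"), each = 500)
  grid <- seq(0.30, 0.52, by = 0.001)
  err <- vapply(grid, function(thr) {
    sum((gc <= thr) != (truth == "lo"))
  }, 0)
  best <- grid[which.min(err)]
  expect_lt(abs(as.numeric(cut) - best), 0.05)
})

test_that("estimate_gc_cutoff refuses degenerate inputs", {
  set.seed(5)
  expect_error(estimate_gc_cutoff(rnorm(500, 0.28, 0.01)), "unimodal")
  expect_error(estimate_gc_cutoff(rnorm(10, 0.3, 0.05)), "at least 20")
  two <- c(rnorm(100, 0.25, 0.005), rnorm(100, 0.60, 0.005))
  cut <- estimate_gc_cutoff(two)
  expect_gt(cut, 0.25)
  expect_lt(cut, 0.60)
})

test_that("gc_cutoff_presets carries the three published cutoffs", {
  p <- gc_cutoff_presets()
  expect_equal(unname(p["b_plumatellae"]), 0.3903)
  expect_equal(unname(p["t_bryosalmonae_fish"]), 0.4080)
  expect_equal(unname(p["t_bryosalmonae_bryozoan"]), 0.3692)
})

test_that("run_decontam conserves contigs and resolves all labels", {
  sim <- simulate_assembly(40, 40, seed = 31)
  hits <- simulate_hits(sim$truth, seed = 32, p_no_hit = 0.3)
  res <- run_decontam(sim$contigs, hits$target, hits$contam,
                      gc_cutoff = 0.3903)
  expect_equal(sum(res$counts), length(sim$contigs))
  expect_equal(unname(res$counts["not_clear"]), 0L)
  expect_true(all(res$report$label %in% c("target", "contamination")))
})

test_that("run_decontam handles hit-only and no-hit corner cases", {
  sim <- simulate_assembly(10, 0, seed = 33)
  hits <- simulate_hits(sim$truth, seed = 34, p_no_hit = 0,
                        evalue_separation = Inf)
  res <- run_decontam(sim$contigs, hits$target, hits$contam,
                      gc_cutoff = 0.39)
  expect_equal(unname(res$counts["target"]), 10L)
  expect_equal(unname(res$counts["contamination"]), 0L)

  # empty hit tables: everything not_clear, rescued by GC
  empty <- hits$target[0, ]
  res2 <- run_decontam(sim$contigs, empty, empty, gc_cutoff = 0.39)
  expect_equal(unname(res2$counts["target"]), 10L)
  expect_true(all(res2$report$rule == "gc_rescue_target"))
})

test_that("run_decontam applies the host-exclusion stage first", {
  sim <- simulate_assembly(6, 0, seed = 35)
  ids <- sim$truth$contig_id
  host <- best_row(ids[1], 1e-90, 400, pid = 95)
  hits <- simulate_hits(sim$truth, seed = 36, p_no_hit = 0)
  res <- run_decontam(sim$contigs, hits$target, hits$contam,
                      host_hits = host, gc_cutoff = 0.39)
  expect_equal(unname(res$counts["host_excluded"]), 1L)
  expect_identical(res$report$label[res$report$contig_id == ids[1]],
                   "host_excluded")
  expect_equal(sum(res$counts), 6L)
})

test_that("run_decontam reports are byte-identical across reruns", {
  sim <- simulate_assembly(20, 20, seed = 41)
  hits <- simulate_hits(sim$truth, seed = 42)
  d1 <- file.path(tempdir(), "dec_run1")
  d2 <- file.path(tempdir(), "dec_run2")
  run_decontam(sim$contigs, hits$target, hits$contam, gc_cutoff = 0.3903,
               out_dir = d1)
  run_decontam(sim$contigs, hits$target, hits$contam, gc_cutoff = 0.3903,
               out_dir = d2)
  for (f in c("classification.tsv", "target.fasta", "gc_length.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("unknown hit-table query ids warn but do not abort", {
  sim <- simulate_assembly(5, 0, seed = 51)
  hits <- simulate_hits(sim$truth, seed = 52, p_no_hit = 0)
  extra <- hits$target
  extra$query_id[1] <- "ghost_contig"
  expect_warning(
    res <- run_decontam(sim$contigs, extra, hits$contam, gc_cutoff = 0.39),
    "ghost_contig")
  expect_equal(sum(res$counts), 5L)
})
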