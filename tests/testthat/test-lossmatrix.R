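mini_cat <- function(rows, ...) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(taxon = r[[1]], category = r[[2]], protein_id = r[[3]],
               status = if (length(r) > 3) r[[4]] else "intact",
               stringsAsFactors = FALSE)
  }))
  catalogue_from_table(df, ...)
}

test_that("catalogue_from_table validates categories, statuses, triples", {
  expect_error(mini_cat(list(c("T1", "kaspase", "p1"))),
               "unknown actor category")
  expect_error(mini_cat(list(c("T1", "caspase", "p1", "maybe"))),
               "unknown status")
  expect_error(mini_cat(list(c("T1", "caspase", "p1"),
                             c("T1", "caspase", "p1"))),
               "duplicate catalogue entry")
  empty <- catalogue_from_table(
    data.frame(taxon = character(), category = character(),
               protein_id = character(), status = character()))
  expect_s3_class(empty, "actor_catalogue")
  expect_length(empty$taxon_order, 0)
})

test_that("the packaged catalogue has the expected shape", {
  cat1 <- table1_catalogue()
  expect_setequal(unique(cat1$entries$taxon),
                  c(parasitism_gradient(), "Caenorhabditis elegans",
                    "Homo sapiens"))
  expect_length(unique(cat1$entries$taxon), 6)
  expect_length(actor_categories(), 10)
})

test_that("build_matrix cells, counts and retention satisfy the invariants", {
  m <- build_matrix(table1_catalogue())
  expect_identical(m$cells, m$counts >= 1L)
  expect_equal(unname(m$retention), unname(rowSums(m$cells)))
  # row-order invariance
  cat1 <- table1_catalogue()
  shuf <- cat1
  set.seed(9)
  shuf$entries <- shuf$entries[sample(nrow(shuf$entries)), ]
  m2 <- build_matrix(shuf)
  expect_identical(m$cells, m2$cells)
  expect_identical(m$counts, m2$counts)
})

test_that("pseudogene entries are absent from cells unless counted in", {
  cat_ <- mini_cat(list(c("T1", "cytochrome_c", "pseudo1", "pseudogene")))
  m <- build_matrix(cat_)
  expect_false(m$cells["T1", "cytochrome_c"])
  expect_equal(m$pseudo["T1", "cytochrome_c"], 1L)
  m2 <- build_matrix(cat_, count_pseudogenes = TRUE)
  expect_true(m2$cells["T1", "cytochrome_c"])
  # absence markers never count either way
  cat2 <- mini_cat(list(c("T1", "p53", "gone", "absent_marker")))
  expect_false(build_matrix(cat2, count_pseudogenes = TRUE)$cells["T1", "p53"])
})

test_that("adding an entry never decreases retention (monotonicity)", {
  rows <- list(c("T1", "caspase", "c1"), c("T1", "iap", "i1"),
               c("T2", "p53", "p1"))
  m1 <- build_matrix(mini_cat(rows))
  m2 <- build_matrix(mini_cat(c(rows, list(c("T2", "calpain", "k1")))))
  expect_true(all(m2$retention[names(m1$retention)] >= m1$retention))
})

test_that("single-entry catalogue gives a 1-cell presence", {
  m <- build_matrix(mini_cat(list(c("OnlyTaxon", "apaf1", "x"))))
  expect_equal(unname(m$retention["OnlyTaxon"]), 1)
  g <- loss_gradient(m, "OnlyTaxon")
  expect_true(g$non_increasing)
})

test_that("loss_gradient verdict flips under order reversal", {
  m <- build_matrix(table1_catalogue())
  fwd <- loss_gradient(m, parasitism_gradient())
  rev_ <- loss_gradient(m, rev(parasitism_gradient()))
  expect_true(fwd$non_increasing)
  expect_false(rev_$non_increasing)
  expect_error(loss_gradient(m, c("Polypodium", "Atlantis")),
               "not in matrix")
})

test_that("catalogue_from_domains applies required-domain rules", {
  hits <- data.frame(
    protein_id = c("p_casp", "p_casp", "p_casp",
                   "p_wd40",
                   "p_calp", "p_calp", "p_calp",
                   "p_apaf", "p_apaf",
                   "p_weak"),
    domain_acc = "-",
    domain_name = c("CARD", "Caspase_P20", "Caspase_P10",
                    "WD40",
                    "Peptidase_C2", "Calpain_III", "EF-hand",
                    "NB-ARC", "WD40",
                    "Caspase_P20"),
    e_value = c(rep(1e-30, 9), 1),   # p_weak fails the e-value gate
    taxon = "TaxA",
    stringsAsFactors = FALSE)
  cat_ <- catalogue_from_domains(hits, evalue_max = 1e-5)
  e <- cat_$entries
  expect_setequal(e$protein_id, c("p_casp", "p_calp", "p_apaf"))
  expect_identical(e$category[e$protein_id == "p_casp"], "caspase")
  expect_match(e$flags[e$protein_id == "p_casp"], "initiator_card")
  expect_identical(e$category[e$protein_id == "p_calp"], "calpain")
  expect_match(e$flags[e$protein_id == "p_calp"], "classical")
  expect_identical(e$category[e$protein_id == "p_apaf"], "apaf1")
  expect_error(catalogue_from_domains(hits, category_map = list()),
               "empty category_map")
})

test_that("write_matrix emits aligned 0/1 and count tables", {
  m <- build_matrix(table1_catalogue())
  f1 <- tempfile(); f2 <- tempfile()
  write_matrix(m, cells_tsv = f1, counts_tsv = f2)
  cells <- utils::read.delim(f1, check.names = FALSE)
  expect_equal(nrow(cells), length(m$taxa))
  expect_equal(sum(cells[cells$taxon == "Myxosporea", -1]), 1)
  counts <- utils::read.delim(f2, check.names = FALSE)
  expect_equal(counts[counts$taxon == "Free-living Cnidaria", "caspase"], 15)
})
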