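test_that("HMMER tblout files parse and order by E-value", {
  path <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c(
    "#                                                               --- full sequence ---- --- best 1 domain ---- --- domain number estimation ----",
    "# target name        accession  query name           accession    E-value  score  bias   E-value  score  bias   exp reg clu  ov env dom rep inc description of target",
    "#------------------- ---------- -------------------- ---------- --------- ------ ----- --------- ------ -----   --- --- --- --- --- --- --- --- ---------------------",
    "sp|P1|NUP60_YEAST    -          Nup60                PF0001       2.3e-40  135.2   8.1   3.1e-40  134.8   8.1   1.0   1   0   0   1   1   1   1 nucleoporin 60",
    "sp|P3|WEAK_YEAST     -          Nup60                PF0001            0.5   12.0   0.0       0.9   11.1   0.0   1.2   1   0   0   1   1   1   1 weak hit",
    "sp|P2|NUP60_POMBE    -          Nup60                PF0001       8.1e-33  110.0   5.0   9.9e-33  109.5   5.0   1.0   1   0   0   1   1   1   1 fission yeast"),
    path)
  tab <- read_hmmer_tblout(path)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$subject_id,
               c("sp|P1|NUP60_YEAST", "sp|P2|NUP60_POMBE",
                 "sp|P3|WEAK_YEAST"))
  expect_equal(tab$evalue, c(2.3e-40, 8.1e-33, 0.5))
  expect_equal(tab$family[1], "Nup60")

  # comment-only file -> empty table
  p2 <- withr::local_tempfile()
  writeLines(c("# nothing", "# here"), p2)
  expect_equal(nrow(read_hmmer_tblout(p2)), 0L)

  # truncated rows report their position
  p3 <- withr::local_tempfile()
  writeLines("sp|P1 - Nup60 PF0001 1e-5", p3)
  expect_error(read_hmmer_tblout(p3), "line 1")
})

test_that("tblout and tabular hit lists agree on ranks for the same hits", {
  tbl_path <- withr::local_tempfile()
  writeLines(c(
    "s1 - fam F 1e-20 80.0 0.0 1e-20 80.0 0.0 1 1 0 0 1 1 1 1 top",
    "s2 - fam F 1e-10 40.0 0.0 1e-10 40.0 0.0 1 1 0 0 1 1 1 1 mid",
    "s3 - fam F 1e-02 10.0 0.0 1e-02 10.0 0.0 1 1 0 0 1 1 1 1 low"),
    tbl_path)
  blast_path <- withr::local_tempfile()
  writeLines(c(
    "fam\ts1\t90.000\t100\t10\t0\t1\t100\t1\t100\t1e-20\t80.0",
    "fam\ts2\t70.000\t100\t30\t0\t1\t100\t1\t100\t1e-10\t40.0",
    "fam\ts3\t30.000\t50\t35\t0\t1\t50\t1\t50\t1e-02\t10.0"),
    blast_path)
  expect_equal(read_hmmer_tblout(tbl_path)$subject_id,
               read_tabular(blast_path)$subject_id)
})

test_that("rank-of-true-hit follows the top-hit criterion", {
  hits <- tibble::tibble(
    subject_id = c("h1", "h2", "h3"), evalue = c(1e-30, 1e-10, 1e-3))
  expect_equal(rank_true_hits(hits, "h1"),
               tibble::tibble(rank = 1L, detected = TRUE,
                              evalue_of_true = 1e-30))
  r3 <- rank_true_hits(hits, "h3")
  expect_equal(r3$rank, 3L)
  expect_false(r3$detected)
  miss <- rank_true_hits(hits, "absent")
  expect_true(is.na(miss$rank))
  expect_false(miss$detected)
  # multi-copy truths take the best-ranked id
  expect_equal(rank_true_hits(hits, c("h3", "h2"))$rank, 2L)
  expect_error(rank_true_hits(hits, character(0)), "truth")
})

test_that("expected-composition tables validate their invariants", {
  cells <- tidyr::expand_grid(species = c("sp1", "sp2"),
                              family = c("f1", "f2"))
  cells$expected <- c(TRUE, TRUE, TRUE, FALSE)
  cells$truth_ids <- c("p11", "p12", "p21", "")
  ec <- expected_composition(cells)
  g <- glance(ec)
  expect_equal(g$n_cells, 4L)
  expect_equal(g$n_expected + g$n_absent, g$n_species * g$n_families)
  # truth ids exactly where expected
  bad <- cells
  bad$truth_ids <- c("p11", "", "p21", "")
  expect_error(expected_composition(bad), "truth ids")
  bad2 <- cells
  bad2$truth_ids <- c("p11", "p12", "p21", "spurious")
  expect_error(expected_composition(bad2), "absent")
  # TSV round-trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expected_composition(ec, path)
  back <- read_expected_composition(path)
  expect_equal(back$species, ec$species)
  expect_equal(back$expected, ec$expected)
  expect_equal(back$truth_ids, ec$truth_ids)
})

test_that("confusion counts score a toy grid by enumeration", {
  cells <- tidyr::expand_grid(species = c("sp1", "sp2"),
                              family = c("f1", "f2"))
  cells$expected <- c(TRUE, TRUE, TRUE, FALSE)
  cells$truth_ids <- c("p11", "p12", "p21", "")
  ec <- expected_composition(cells)
  records <- tibble::tibble(
    species = c("sp1", "sp1", "sp2"), family = c("f1", "f2", "f1"),
    rank = c(1L, 2L, 1L), detected = c(TRUE, FALSE, TRUE))
  absent <- tibble::tibble(species = "sp2", family = "f2",
                           min_evalue = 0.5)
  cc <- confusion(ec, records, absent, fp_evalue = 1e-5)
  expect_equal(glance(cc)[, c("TP", "FN", "FP", "TN")],
               tibble::tibble(TP = 2L, FN = 1L, FP = 0L, TN = 1L))
  # the same absent call below the threshold becomes an FP
  cc2 <- confusion(ec, records, absent, fp_evalue = 1)
  expect_equal(cc2$FP, 1L)
  expect_equal(cc2$TN, 0L)
  # all-detected records zero the FN cell
  all_rec <- dplyr::mutate(records, detected = TRUE, rank = 1L)
  expect_equal(confusion(ec, all_rec, absent)$FN, 0L)
  # incomplete records are an error naming the cells
  expect_error(confusion(ec, records[1:2, ], absent), "sp2/f1")
})

test_that("TPR/FNR arithmetic reproduces the benchmark table rates", {
  expect_equal(tpr(confusion_counts(375, 31)), 92.4)
  expect_equal(fnr(confusion_counts(375, 31)), 7.6)
  expect_equal(tpr(confusion_counts(246, 63)), 79.6)
  expect_equal(fnr(confusion_counts(246, 63)), 20.4)
  expect_equal(tpr(confusion_counts(0, 5)), 0)
  expect_error(tpr(confusion_counts(0, 0)), "undefined")
  # complementarity to rounding
  cc <- confusion_counts(113, 29)
  expect_equal(tpr(cc) + fnr(cc), 100, tolerance = 0.1)
})

test_that("method deltas come out in percentage points", {
  a <- confusion_counts(375, 31)
  b <- confusion_counts(246, 63)
  expect_equal(compare_methods(a, b), 12.8)
  expect_equal(compare_methods(a, a), 0)
})

test_that("rank matrices render the grid with summary counts", {
  cells <- tidyr::expand_grid(species = c("sp1", "sp2"),
                              family = c("f1", "f2"))
  cells$expected <- c(TRUE, TRUE, TRUE, FALSE)
  cells$truth_ids <- c("p11", "p12", "p21", "")
  ec <- expected_composition(cells)
  records <- tibble::tibble(
    species = c("sp1", "sp1", "sp2"), family = c("f1", "f2", "f1"),
    rank = c(1L, 5L, NA), detected = c(TRUE, FALSE, FALSE))
  rm <- rank_matrix_report(records, ec)
  expect_equal(dim(rm), c(2L, 3L))
  expect_equal(rm$f1, c("1", "-"))
  expect_equal(rm$f2, c("5", "."))
  s <- attr(rm, "summary")
  expect_equal(c(s$detected, s$ranked_lower, s$not_detected),
               c(1L, 1L, 1L))
  plt <- autoplot(rm)
  expect_s3_class(plt, "ggplot")
})
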