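test_that("self-alignment recovers the full diagonal score", {
  s <- "MKVLAW"
  aln <- align_to_master(s, s, bl62)
  expect_equal(aln$score,
               sum(diag(bl62$scores[aa_vec(s), aa_vec(s)])))
  expect_equal(aln$master_start, 1L)
  expect_equal(aln$master_end, nchar(s))
  expect_equal(aln$pairs$master_pos, aln$pairs$member_pos)
})

test_that("pairwise local alignment equals the exhaustive oracle", {
  aln <- align_to_master("MKVLAW", "KVLA", bl62)
  expect_equal(aln$score, oracle_pair_score("MKVLAW", "KVLA", bl62))
  set.seed(11)
  for (i in 1:120) {
    a <- random_protein(sample(2:6, 1))
    b <- random_protein(sample(2:8, 1))
    expect_equal(align_to_master(a, b, bl62)$score,
                 oracle_pair_score(a, b, bl62),
                 info = paste(a, b))
  }
})

test_that("an all-X member yields the empty alignment", {
  aln <- align_to_master("MKVLAW", "XXXX", bl62)
  expect_equal(aln$score, 0)
  expect_equal(nrow(aln$pairs), 0L)
})

test_that("master-slave MSA covers the trivial shapes", {
  one <- family_seed_set("f", tibble::tibble(id = "m", residues = "MKVLAW"))
  msa1 <- build_msa(one, bl62)
  expect_equal(ncol(msa1$ali), 1L)
  expect_equal(paste(msa1$ali[, 1], collapse = ""), "MKVLAW")

  twin <- family_seed_set("f", tibble::tibble(
    id = c("m", "c"), residues = c("MKVLAWHE", "MKVLAWHE")),
    master_id = "m")
  msa2 <- build_msa(twin, bl62)
  expect_equal(msa2$ali[, "m"], msa2$ali[, "c"])
})

test_that("divergent members land in master coordinates as constructed", {
  fam <- toy_family_tbl("f", n = 5, core_length = 80, divergence = 0.3,
                        seed = 5)
  seeds <- family_seed_set("f", fam[-1, ], master_id = fam$id[2])
  msa <- build_msa(seeds, bl62)
  expect_equal(ncol(msa$ali), 5L)
  expect_equal(nrow(msa$ali), nchar(fam$residues[2]))
  # with indel_rate 0 every member aligns gap-free along the diagonal:
  # wherever a member is covered, the cell holds its residue at that site
  for (k in seq_len(5)) {
    mem <- fam$id[k + 1]
    col <- msa$ali[, mem]
    covered <- which(!is.na(col))
    expect_gt(length(covered), 0.9 * nrow(msa$ali))
    expect_equal(col[covered], aa_vec(fam$residues[k + 1])[covered])
  }
  # members below the coverage floor are excluded with a log entry
  frag <- dplyr::bind_rows(fam[-1, ], tibble::tibble(
    id = "frag", description = "", residues = substr(fam$residues[2], 1, 20)))
  seeds2 <- family_seed_set("f", frag, master_id = fam$id[2])
  msa2 <- build_msa(seeds2, bl62)
  expect_false("frag" %in% colnames(msa2$ali))
  expect_true("frag" %in% msa2$excluded$id)
})

test_that("position-based weights follow the 1/(r s) rule", {
  mk_msa <- function(rows) {
    ali <- do.call(cbind, lapply(rows, aa_vec))
    colnames(ali) <- paste0("m", seq_along(rows))
    structure(list(
      master = tibble::tibble(id = "m1", residues = rows[[1]]),
      ali = ali, member_ids = colnames(ali),
      excluded = tibble::tibble(), insertions = tibble::tibble()),
      class = "master_msa")
  }
  # n identical rows: symmetric weights 1/n
  w <- position_based_weights(mk_msa(list("MKV", "MKV", "MKV", "MKV")))
  expect_equal(unname(w), rep(0.25, 4))
  # any 2-row MSA: 0.5 / 0.5
  w2 <- position_based_weights(mk_msa(list("MKVA", "WEDC")))
  expect_equal(unname(w2), c(0.5, 0.5))
  # hand-computed: rows AA, AA, AC ->
  # col1: r=1, A shared by 3 -> 1/3 each; col2: r=2, A by 2 -> 1/4, C -> 1/2
  # means: (1/3+1/4)/2, same, (1/3+1/2)/2 -> 7/24, 7/24, 5/12 (sum 1)
  w3 <- position_based_weights(mk_msa(list("AA", "AA", "AC")))
  expect_equal(unname(w3), c(7 / 24, 7 / 24, 5 / 12))
})

test_that("effective observations count mean distinct residues", {
  mk_msa <- function(rows) {
    ali <- do.call(cbind, lapply(rows, aa_vec))
    colnames(ali) <- paste0("m", seq_along(rows))
    structure(list(
      master = tibble::tibble(id = "m1", residues = rows[[1]]),
      ali = ali, member_ids = colnames(ali),
      excluded = tibble::tibble(), insertions = tibble::tibble()),
      class = "master_msa")
  }
  expect_equal(effective_observations(mk_msa(list("AAA", "AAA"))), 1)
  # columns {A},{A,C} -> mean(1, 2) = 1.5
  expect_equal(effective_observations(mk_msa(list("AA", "AC"))), 1.5)
  # random fixture equals an independent recount
  set.seed(3)
  rows <- replicate(10, random_protein(12))
  msa <- mk_msa(as.list(rows))
  chars <- do.call(rbind, lapply(rows, aa_vec))
  recount <- mean(apply(chars, 2, function(col) length(unique(col))))
  expect_equal(effective_observations(msa), recount)
})

test_that("pseudocount mixing hits its closed forms", {
  obs <- stats::setNames(numeric(20), names(bl62$background_freqs))
  obs["A"] <- 1
  # beta = 0: observed frequencies pass through
  expect_equal(pseudo_frequencies(obs, bl62, alpha = 3, beta = 0), obs)
  # alpha = 0: pure matrix-derived target frequencies
  p <- bl62$background_freqs
  s20 <- bl62$scores[names(p), names(p)]
  cond <- sweep(exp(bl62$ungapped_lambda * s20) * p, 2,
                colSums(exp(bl62$ungapped_lambda * s20) * p), "/")
  g <- as.numeric(cond %*% obs)
  expect_equal(unname(pseudo_frequencies(obs, bl62, alpha = 0, beta = 5)),
               g / sum(g))
  # direct evaluation of the mixture formula at alpha 1, beta 10
  q <- pseudo_frequencies(obs, bl62, alpha = 1, beta = 10)
  expect_equal(unname(q), unname((1 * obs + 10 * g / sum(g)) / 11))
  expect_equal(sum(q), 1, tolerance = 1e-9)
  expect_true(all(q > 0))
  expect_error(pseudo_frequencies(obs, bl62, alpha = 0, beta = 0),
               "alpha")
})

test_that("single-sequence profiles peak on the master residue", {
  set.seed(21)
  for (i in 1:5) {
    s <- random_protein(30)
    seeds <- family_seed_set("f", tibble::tibble(id = "m", residues = s))
    pssm <- build_family_pssm(seeds, bl62)
    midx <- match(aa_vec(s), colnames(pssm$scores))
    master_scores <- pssm$scores[cbind(seq_len(nchar(s)), midx)]
    row_max <- apply(pssm$scores[, 1:20], 1, max)
    expect_equal(master_scores, row_max)
    expect_true(all(master_scores > 0))
  }
})

test_that("PSSM rows satisfy the log-odds normalization band", {
  fam <- toy_family_tbl("f", n = 6, core_length = 60, divergence = 0.25,
                        seed = 9)
  seeds <- family_seed_set("f", fam[-1, ])
  pssm <- build_family_pssm(seeds, bl62)
  expect_equal(unname(rowSums(pssm$weighted_freqs)),
               rep(1, pssm$length), tolerance = 1e-6)
  p <- pssm$background_freqs
  z <- rowSums(sweep(exp(pssm$scale_lambda *
                           pssm$scores[, 1:20, drop = FALSE]), 2, p, "*"))
  expect_true(all(z >= 0.8 & z <= 1.25))
})

test_that("profiles are invariant to member order and duplication", {
  fam <- toy_family_tbl("f", n = 5, core_length = 50, divergence = 0.2,
                        seed = 13)
  members <- fam[-1, ]
  seeds_a <- family_seed_set("f", members, master_id = members$id[1])
  perm <- members[c(3, 1, 5, 2, 4), ]
  seeds_b <- family_seed_set("f", perm, master_id = members$id[1])
  pa <- build_family_pssm(seeds_a, bl62)
  pb <- build_family_pssm(seeds_b, bl62)
  expect_identical(pa$scores, pb$scores)
  # full duplication of the member set changes nothing (weighting)
  dup <- dplyr::bind_rows(
    members, dplyr::mutate(members, id = paste0(id, "_copy")))
  pd <- build_family_pssm(
    family_seed_set("f", dup, master_id = members$id[1]), bl62)
  expect_identical(pa$scores, pd$scores)
})

test_that("background-frequency columns score zero", {
  obs <- bl62$background_freqs
  q <- pseudo_frequencies(obs, bl62, alpha = 5, beta = 0)
  sc <- round(log(q / bl62$background_freqs) / (log(2) / 2))
  expect_equal(unname(sc), rep(0, 20))
})

test_that("PSSM ASCII files round-trip", {
  fam <- toy_family_tbl("f", n = 4, core_length = 40, divergence = 0.2,
                        seed = 17)
  pssm <- build_family_pssm(family_seed_set("famX", fam[-1, ]), bl62)
  path <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(pssm, path)
  back <- read_pssm(path)
  expect_identical(back$scores, pssm$scores)
  expect_identical(back$family, pssm$family)
  expect_identical(back$consensus, pssm$consensus)
  expect_equal(back$scale_lambda, pssm$scale_lambda)
  expect_equal(back$gapped_K, pssm$gapped_K)
  expect_equal(back$gap_open, pssm$gap_open)
  expect_equal(back$pseudocount_beta, pssm$pseudocount_beta)
  expect_equal(back$background_freqs, pssm$background_freqs)
  # frequencies round-trip at the printed 4-decimal precision
  expect_lte(max(abs(back$weighted_freqs - pssm$weighted_freqs)),
             5.01e-5)

  # header/body length mismatch is a parse error
  lines <- readLines(path)
  truncated <- withr::local_tempfile()
  writeLines(head(lines, length(lines) - 3L), truncated)
  expect_error(read_pssm(truncated), "length")
})

test_that("a hand-written two-column PSSM file parses to its scores", {
  path <- withr::local_tempfile(fileext = ".pssm")
  sc1 <- c(5L, rep(-2L, 19))
  sc2 <- c(rep(-3L, 5), 7L, rep(-3L, 14))
  fr <- sprintf("%.4f", rep(0.05, 20))
  writeLines(c(
    "# family:mini", "# length:2", "# lambda:0.34657359027997264",
    "# K:0.041", "# gap:11,1", "# beta:10",
    paste0("# background:",
           paste(sprintf("%.17g", rep(0.05, 20)), collapse = ",")),
    paste(c("1", "A", sc1, fr), collapse = "\t"),
    paste(c("2", "Q", sc2, fr), collapse = "\t")), path)
  pssm <- read_pssm(path)
  expect_equal(pssm$length, 2L)
  expect_equal(pssm$consensus, "AQ")
  expect_equal(unname(pssm$scores[1, 1:20]), as.integer(sc1))
  expect_equal(unname(pssm$scores[2, 1:20]), as.integer(sc2))
  expect_equal(unname(pssm$scores[, "X"]), c(-1L, -1L))
})
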