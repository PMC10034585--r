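# Shared fixtures and independent oracles for the alignment suite.

bl62 <- load_substitution_matrix("BLOSUM62")

# internal utilities exercised across the suite
aa_index_pub <- profscan:::aa_index
random_decoys_pub <- profscan:::random_decoys

aa_vec <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

random_protein <- function(n, p = bl62$background_freqs) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# --- Exhaustive local-alignment oracle -------------------------------------
#
# A local alignment with affine gaps is a monotone matching of profile
# positions to subject positions; unmatched residues between consecutive
# matches form one deletion and/or one insertion gap (splitting a gap
# can only add open penalties, so the optimum is attained on this
# family). Enumerates every monotone matching — C(m+n, m) of them at
# m = 6, n = 8 — and maximizes score directly. Completely independent
# of the dynamic-programming implementation.

oracle_matchings_cache <- new.env(parent = emptyenv())

oracle_matchings <- function(m, n) {
  key <- paste(m, n)
  if (!is.null(oracle_matchings_cache[[key]])) {
    return(oracle_matchings_cache[[key]])
  }
  out <- list()
  for (k in seq_len(min(m, n))) {
    Q <- t(utils::combn(m, k))
    S <- t(utils::combn(n, k))
    QQ <- Q[rep(seq_len(nrow(Q)), each = nrow(S)), , drop = FALSE]
    SS <- S[rep(seq_len(nrow(S)), times = nrow(Q)), , drop = FALSE]
    out[[k]] <- list(Q = QQ, S = SS, k = k)
  }
  oracle_matchings_cache[[key]] <- out
  out
}

# prof: m x 21 integer score matrix; subj_idx: residue codes
oracle_local_align_score <- function(prof, subj_idx, gap_open, gap_ext) {
  m <- nrow(prof)
  n <- length(subj_idx)
  best <- 0L
  for (ms in oracle_matchings(m, n)) {
    k <- ms$k
    match_sc <- matrix(prof[cbind(as.vector(ms$Q),
                                  subj_idx[as.vector(ms$S)])],
                       ncol = k)
    total <- rowSums(match_sc)
    if (k > 1L) {
      dq <- ms$Q[, -1L, drop = FALSE] - ms$Q[, -k, drop = FALSE] - 1L
      ds <- ms$S[, -1L, drop = FALSE] - ms$S[, -k, drop = FALSE] - 1L
      gap <- rowSums((dq > 0L) * (gap_open + gap_ext * dq)) +
        rowSums((ds > 0L) * (gap_open + gap_ext * ds))
      total <- total - gap
    }
    best <- max(best, max(total))
  }
  best
}

oracle_pair_score <- function(master, member, matrix,
                              gap_open = 11L, gap_ext = 1L) {
  mi <- match(aa_vec(master), colnames(matrix$scores))
  prof <- matrix$scores[mi, , drop = FALSE]
  si <- match(aa_vec(member), colnames(matrix$scores))
  oracle_local_align_score(prof, si, gap_open, gap_ext)
}

# --- Quadratic homopolymer-bias oracle -------------------------------------
# max over all O(n^2) substrings of the per-position score sum
oracle_homopolymer <- function(seq, residue, matrix) {
  s <- unname(matrix$scores[residue,
                            match(aa_vec(seq), colnames(matrix$scores))])
  n <- length(s)
  best <- 0L
  for (i in seq_len(n)) {
    acc <- 0L
    for (j in i:n) {
      acc <- acc + s[j]
      if (acc > best) best <- acc
    }
  }
  best
}

# small random PSSM for search-level tests: integer scores in a
# BLOSUM-like range, X column fixed at -1
random_toy_pssm <- function(L, scores = NULL) {
  sc <- matrix(-1L, L, 21L, dimnames = list(NULL, c(
    "A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
    "P","S","T","W","Y","V","X")))
  if (is.null(scores)) {
    sc[, 1:20] <- sample(-4:6, L * 20L, replace = TRUE)
  } else {
    sc[, 1:20] <- scores
  }
  cons <- colnames(sc)[apply(sc[, 1:20, drop = FALSE], 1, which.max)]
  structure(list(
    family = "toy", length = L, consensus = paste(cons, collapse = ""),
    scores = sc,
    weighted_freqs = matrix(1 / 20, L, 20,
                            dimnames = list(NULL, colnames(sc)[1:20])),
    background_freqs = bl62$background_freqs,
    scale_lambda = log(2) / 2, gapped_K = 0.041,
    gap_open = 11L, gap_extend = 1L, pseudocount_beta = 10,
    flagged_columns = integer(0)), class = "pssm")
}

# deterministic tiny seed families for harvest/benchmark fixtures
toy_family_tbl <- function(fam, n, core_length, divergence, seed,
                           matrix = bl62) {
  spec <- synthetic_family_spec(fam, core_length = core_length,
                                n_members = n, divergence = divergence,
                                indel_rate = 0, rng_seed = seed)
  sample_family(spec, matrix)
}
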