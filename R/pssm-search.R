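#' Align a PSSM against a subject sequence
#'
#' Position-specific Smith-Waterman with affine gaps: the match score of
#' profile position `i` against subject residue `b` is `scores[i, b]`;
#' `X` in the subject scores -1 at every position. Only the best HSP is
#' returned (the "max hits per sequence = 1" convention).
#'
#' @param pssm A `pssm`.
#' @param subject Residue string or single-row sequence tibble.
#' @param gap_open,gap_extend Gap penalties; default to those recorded
#'   in the PSSM.
#' @return A one-row tibble (HSP: `query_start`, `query_end`,
#'   `subject_start`, `subject_end`, `raw_score`, `align_len`, `nident`,
#'   `mismatches`, `gap_opens`) or `NULL` when no positive-scoring
#'   local alignment exists (e.g. an all-X subject).
#' @export
sw_pssm_align <- function(pssm, subject, gap_open = pssm$gap_open,
                          gap_extend = pssm$gap_extend) {
  stopifnot(inherits(pssm, "pssm"))
  if (is.data.frame(subject)) subject <- subject$residues[[1]]
  cons <- aa_index(pssm$consensus)
  res <- sw_profile_cpp(pssm$scores, cons, aa_index(subject),
                        as.integer(gap_open), as.integer(gap_extend))
  if (res$score <= 0) return(NULL)
  tibble::tibble(
    query_start = min(res$q_pos), query_end = max(res$q_pos),
    subject_start = min(res$s_pos), subject_end = max(res$s_pos),
    raw_score = res$score, align_len = res$align_len,
    nident = res$nident, mismatches = res$mismatches,
    gap_opens = res$gap_opens)
}

#' Karlin-Altschul bit score
#'
#' \deqn{S' = \frac{\lambda S - \ln K}{\ln 2}}
#'
#' @param raw Integer raw alignment score.
#' @param lambda Scale parameter in nats per score unit (`> 0`).
#' @param K Karlin-Altschul K (`> 0`).
#' @return Bit score, strictly increasing in `raw`.
#' @export
bit_score <- function(raw, lambda, K) {
  stopifnot(lambda > 0, K > 0)
  (lambda * raw - log(K)) / log(2)
}

#' E-value from a bit score and a search space
#'
#' \deqn{E = m \, n \, 2^{-S'}}
#' Takes the (effective) profile length `m` and database residue count
#' `n` as given; [search_proteome()] applies the edge correction before
#' calling.
#'
#' @param bit Bit score.
#' @param m Profile length (`> 0`).
#' @param n Database residues (`> 0`).
#' @return Expected chance-hit count (`>= 0`); halves when the bit score
#'   grows by 1, linear in `n`.
#' @export
evalue <- function(bit, m, n) {
  stopifnot(m > 0, n > 0)
  m * n * 2^(-bit)
}

# Profile relative entropy per position (nats): H = mean_i sum_a t_ia *
# lambda * s_ia with target freqs t_ia ~ p_a exp(lambda s_ia). Floored
# to keep the edge-correction length finite for information-poor
# profiles.
profile_entropy <- function(pssm) {
  s <- pssm$scores[, AA20, drop = FALSE]
  lam <- pssm$scale_lambda
  t_ <- sweep(exp(lam * s), 2, pssm$background_freqs, "*")
  t_ <- t_ / rowSums(t_)
  H <- mean(rowSums(t_ * lam * s))
  max(H, 0.01)
}

# Standard BLAST-style edge correction: expected HSP length l =
# floor(ln(K m n) / H); effective lengths floored to stay positive.
effective_search_space <- function(pssm, n_residues, n_seqs) {
  m <- pssm$length
  H <- profile_entropy(pssm)
  l <- max(0, floor(log(max(pssm$gapped_K * m * n_residues, 1)) / H))
  m_eff <- max(1, m - l)
  n_eff <- max(n_seqs, n_residues - n_seqs * l)
  list(m_eff = m_eff, n_eff = n_eff, l = l)
}

#' Composition-based rescaling of score statistics
#'
#' Re-solves the scale parameter for a specific subject composition:
#' `lambda_adj` is the positive root of
#' \deqn{\sum_a q_a \frac{1}{L} \sum_i e^{\lambda s_{ia}} = 1}
#' where `q` is the subject residue composition (with a pseudocount of
#' one per residue type). Subjects enriched in residues the profile
#' scores highly obtain a smaller `lambda_adj`, deflating their bit
#' scores — the compositional adjustment that keeps biased sequences
#' from accumulating inflated significance. Subjects shorter than 30
#' residues are skipped (global lambda returned): their compositions
#' are too noisy to calibrate on.
#'
#' @param pssm A `pssm`.
#' @param subject Residue string or single-row sequence tibble.
#' @return Adjusted lambda (nats per score unit); falls back to the
#'   PSSM's `scale_lambda` with a warning when no root exists in
#'   `(0, 10 * lambda)`.
#' @export
composition_rescale <- function(pssm, subject) {
  if (is.data.frame(subject)) subject <- subject$residues[[1]]
  idx <- aa_index(subject)
  idx <- idx[idx <= 20L]  # masked residues carry no compositional signal
  if (length(idx) < 30L) return(pssm$scale_lambda)
  counts <- tabulate(idx, nbins = 20L) + 1
  q <- counts / sum(counts)
  s <- pssm$scores[, AA20, drop = FALSE]
  # profile scores take few distinct integer values: evaluate the
  # normalization sum through a per-residue score histogram so each
  # root-finder step costs O(#values x 20), not O(L x 20) exps
  vals <- sort(unique(as.vector(s)))
  hist20 <- vapply(seq_len(20L), function(j) {
    tabulate(match(s[, j], vals), nbins = length(vals))
  }, integer(length(vals)))
  qn <- q / nrow(s)
  f <- function(l) sum(qn * (exp(l * vals) %*% hist20)) - 1
  lam0 <- pssm$scale_lambda
  upper <- 10 * lam0
  # f(0) = 0 identically; seek the nontrivial positive root by
  # bracketing between a point where f < 0 and one where f > 0
  lo <- lam0 / 100
  if (f(lo) >= 0) {
    warning("expected profile score non-negative under subject ",
            "composition; using global lambda")
    return(lam0)
  }
  hi <- lam0
  while (f(hi) < 0 && hi < upper) hi <- hi * 1.5
  if (f(hi) < 0) {
    warning("no composition-rescaled lambda in (0, 10*lambda); ",
            "using global lambda")
    return(lam0)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Scan a proteome with a PSSM
#'
#' Exhaustive position-specific Smith-Waterman over every database
#' sequence (no seeding heuristics), Karlin-Altschul E-values with the
#' standard edge correction, optional composition-based statistics, and
#' the hit-list shape used for nucleoporin screening: best HSP per
#' subject, E-value cutoff, at most `max_target_sequences` subjects.
#'
#' @param pssm A `pssm`.
#' @param db Sequence tibble (the proteome).
#' @param evalue_cutoff Keep hits with `E <= evalue_cutoff`.
#' @param max_target_sequences Hit-list cap (default 20).
#' @param max_hsps HSPs per subject (only 1, the screening-protocol
#'   hit-list shape, is supported).
#' @param cbs `TRUE` to rescale statistics per subject composition.
#' @param proteome_id Label recorded on the hit table.
#' @return A `hit_tbl`: tibble in BLAST outfmt-6 column layout
#'   (`family`, `subject_id`, `pident`, `length`, `mismatch`,
#'   `gapopen`, `qstart`, `qend`, `sstart`, `send`, `evalue`,
#'   `bit_score`), sorted by ascending E (ties: higher bit score, then
#'   subject id), with the search space in attributes.
#' @export
search_proteome <- function(pssm, db, evalue_cutoff = 10,
                            max_target_sequences = 20L, max_hsps = 1L,
                            cbs = TRUE, proteome_id = "db") {
  stopifnot(inherits(pssm, "pssm"))
  db <- as_seq_tbl(db)
  if (nrow(db) == 0L) stop("empty database")
  if (max_hsps != 1L) stop("only max_hsps = 1 is supported")

  n_res <- sum(nchar(db$residues))
  space <- effective_search_space(pssm, n_res, nrow(db))
  cons <- aa_index(pssm$consensus)

  subj_idx <- lapply(db$residues, aa_index)
  raw <- sw_profile_scores_cpp(pssm$scores, subj_idx,
                               pssm$gap_open, pssm$gap_extend)

  keep <- integer(0)
  keep_bits <- numeric(0)
  keep_E <- numeric(0)
  for (k in seq_len(nrow(db))) {
    if (raw[k] <= 0) next
    # cheap global-lambda screen: composition rescaling moves lambda by
    # far less than the ~20 bits this margin allows, so subjects hopeless
    # under global statistics are not re-solved
    bits0 <- bit_score(raw[k], pssm$scale_lambda, pssm$gapped_K)
    if (evalue(bits0, space$m_eff, space$n_eff) > evalue_cutoff * 1e6) next
    lam <- if (cbs) composition_rescale(pssm, db$residues[k]) else
      pssm$scale_lambda
    bits <- bit_score(raw[k], lam, pssm$gapped_K)
    E <- evalue(bits, space$m_eff, space$n_eff)
    if (E > evalue_cutoff) next
    keep <- c(keep, k)
    keep_bits <- c(keep_bits, bits)
    keep_E <- c(keep_E, E)
  }
  if (length(keep) > 0L) {
    ord <- order(keep_E, -keep_bits, db$id[keep])
    ord <- utils::head(ord, max_target_sequences)
    alns <- lapply(keep[ord], function(k) {
      sw_profile_cpp(pssm$scores, cons, subj_idx[[k]],
                     pssm$gap_open, pssm$gap_extend)
    })
    hits <- tibble::tibble(
      family = pssm$family, subject_id = db$id[keep[ord]],
      pident = vapply(alns, function(a) 100 * a$nident / a$align_len,
                      numeric(1)),
      length = vapply(alns, `[[`, integer(1), "align_len"),
      mismatch = vapply(alns, `[[`, integer(1), "mismatches"),
      gapopen = vapply(alns, `[[`, integer(1), "gap_opens"),
      qstart = vapply(alns, function(a) min(a$q_pos), integer(1)),
      qend = vapply(alns, function(a) max(a$q_pos), integer(1)),
      sstart = vapply(alns, function(a) min(a$s_pos), integer(1)),
      send = vapply(alns, function(a) max(a$s_pos), integer(1)),
      evalue = keep_E[ord], bit_score = keep_bits[ord])
  } else {
    hits <- empty_hit_tbl(pssm$family)
  }
  new_hit_tbl(hits, family = pssm$family, proteome_id = proteome_id,
              m = pssm$length, n_residues = n_res, n_seqs = nrow(db))
}

empty_hit_tbl <- function(family = character(0)) {
  tibble::tibble(
    family = character(), subject_id = character(), pident = numeric(),
    length = integer(), mismatch = integer(), gapopen = integer(),
    qstart = integer(), qend = integer(), sstart = integer(),
    send = integer(), evalue = numeric(), bit_score = numeric())
}

new_hit_tbl <- function(x, family = NA_character_,
                        proteome_id = NA_character_,
                        m = NA_integer_, n_residues = NA_integer_,
                        n_seqs = NA_integer_) {
  structure(tibble::as_tibble(x),
            family = family, proteome_id = proteome_id,
            search_space = c(m = m, n_residues = n_residues,
                             n_seqs = n_seqs),
            class = c("hit_tbl", class(tibble::tibble())))
}

#' Write a hit table in BLAST tabular (outfmt 6) layout
#'
#' Twelve tab-separated columns: qseqid (family), sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore.
#'
#' @param hits A `hit_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tabular <- function(hits, path) {
  lines <- vapply(seq_len(nrow(hits)), function(i) {
    paste(c(hits$family[i], hits$subject_id[i],
            sprintf("%.3f", hits$pident[i]),
            hits$length[i], hits$mismatch[i], hits$gapopen[i],
            hits$qstart[i], hits$qend[i], hits$sstart[i], hits$send[i],
            sprintf("%.3g", hits$evalue[i]),
            sprintf("%.1f", hits$bit_score[i])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' @param path Path to a 12-column tab-separated hit file.
#' @return A `hit_tbl` sorted as read (files written by
#'   [write_tabular()] are already rank-ordered).
#' @export
read_tabular <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(new_hit_tbl(empty_hit_tbl()))
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 12L) {
      stop("tabular parse error at line ", i, ": expected 12 columns, got ",
           length(parts))
    }
    nums <- suppressWarnings(as.numeric(parts[3:12]))
    if (anyNA(nums)) stop("tabular parse error at line ", i,
                          ": non-numeric field")
    tibble::tibble(
      family = parts[1], subject_id = parts[2], pident = nums[1],
      length = as.integer(nums[2]), mismatch = as.integer(nums[3]),
      gapopen = as.integer(nums[4]), qstart = as.integer(nums[5]),
      qend = as.integer(nums[6]), sstart = as.integer(nums[7]),
      send = as.integer(nums[8]), evalue = nums[9], bit_score = nums[10])
  })
  tab <- dplyr::bind_rows(rows)
  new_hit_tbl(tab, family = tab$family[1])
}
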