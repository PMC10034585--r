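#' Construct a family seed set
#'
#' A curated set of homologs for one protein family, anchored on a
#' designated representative (master) sequence, together with the
#' family-specific inclusion E-value used during iterative harvesting.
#' Repeat-rich families conventionally carry a more stringent threshold.
#' One entry may represent two subunit names (e.g. families whose two
#' mature subunits are encoded by a single gene); record that in `notes`.
#'
#' @param family Family name (e.g. `"Nup60"`).
#' @param members Sequence tibble of family members.
#' @param master_id Id of the representative; default = longest member.
#' @param inclusion_evalue Family-specific harvest inclusion threshold.
#' @param notes Free-text annotation.
#' @return Object of class `family_seeds`.
#' @export
family_seed_set <- function(family, members, master_id = NULL,
                            inclusion_evalue = 1e-5, notes = "") {
  members <- as_seq_tbl(members)
  if (nrow(members) == 0L) stop("family seed set needs >= 1 member")
  if (anyDuplicated(members$id)) stop("duplicate member ids")
  if (is.null(master_id)) {
    master_id <- members$id[which.max(nchar(members$residues))]
  }
  if (!master_id %in% members$id) stop("master_id not among members")
  # 0 is allowed as the degenerate "admit nothing" harvest threshold
  stopifnot(inclusion_evalue >= 0)
  structure(list(family = family, members = members,
                 master_id = master_id,
                 inclusion_evalue = inclusion_evalue, notes = notes),
            class = "family_seeds")
}

#' @export
print.family_seeds <- function(x, ...) {
  cat("<family_seeds> ", x$family, ": ", nrow(x$members),
      " member(s), master ", x$master_id,
      ", inclusion E <= ", format(x$inclusion_evalue), "\n", sep = "")
  invisible(x)
}

#' Optimal local alignment of a member against the family master
#'
#' Smith-Waterman with affine gaps (gap of length g costs
#' `gap_open + g * gap_extend`), returning only the single best-scoring
#' HSP — the "one hit per sequence" behavior used when aligning family
#' members to the representative. Traceback tie-breaks prefer diagonal
#' over up over left, and the best cell is the leftmost maximum, so
#' results are platform-independent.
#'
#' @param master,member Residue strings or single-row sequence tibbles.
#' @param matrix A `subst_matrix`.
#' @param gap_open,gap_extend Positive gap penalties.
#' @return List with `score` (0 for no positive-scoring alignment),
#'   `master_start`, `master_end`, `member_start`, `member_end` (1-based
#'   inclusive) and `pairs`, a tibble of matched positions
#'   (`master_pos`, `member_pos`).
#' @export
align_to_master <- function(master, member, matrix,
                            gap_open = 11L, gap_extend = 1L) {
  if (is.data.frame(master)) master <- master$residues[[1]]
  if (is.data.frame(member)) member <- member$residues[[1]]
  stopifnot(gap_open > 0, gap_extend > 0)
  mi <- aa_index(master)
  prof <- matrix$scores[mi, , drop = FALSE]
  res <- sw_profile_cpp(prof, mi, aa_index(member),
                        as.integer(gap_open), as.integer(gap_extend))
  pairs <- tibble::tibble(master_pos = res$q_pos, member_pos = res$s_pos)
  list(score = res$score,
       master_start = if (res$score > 0) min(res$q_pos) else NA_integer_,
       master_end = if (res$score > 0) max(res$q_pos) else NA_integer_,
       member_start = if (res$score > 0) min(res$s_pos) else NA_integer_,
       member_end = if (res$score > 0) max(res$s_pos) else NA_integer_,
       pairs = pairs)
}

#' Build a master-slave multiple alignment
#'
#' Aligns every member of a seed set to the master with
#' [align_to_master()] and stacks the aligned residues into master
#' coordinates: one column per master position, holding for each member
#' an aligned residue, a gap (`-`, an unmatched master position inside
#' the member's aligned span), or not-covered (`NA`, outside the span).
#' Insertions relative to the master are dropped from the profile and
#' only counted in the insertion log. Members whose best HSP spans less
#' than `min_coverage` of the master are excluded with a log entry.
#'
#' @param seeds A `family_seeds` object.
#' @param matrix A `subst_matrix`.
#' @param min_coverage Minimum fraction of master length the HSP must
#'   span for a member to enter the alignment.
#' @param gap_open,gap_extend Gap penalties passed to the aligner.
#' @return Object of class `master_msa`: `master` (single-row seq
#'   tibble), `ali` (L x n character matrix, columns = member ids),
#'   `member_ids`, `excluded` (tibble id/reason), `insertions` (tibble
#'   id/n_inserted).
#' @export
build_msa <- function(seeds, matrix, min_coverage = 0.5,
                      gap_open = 11L, gap_extend = 1L) {
  stopifnot(inherits(seeds, "family_seeds"))
  master <- seeds$members[seeds$members$id == seeds$master_id, ]
  L <- nchar(master$residues)
  mchars <- strsplit(master$residues, "", fixed = TRUE)[[1]]

  cols <- list()
  excluded <- list()
  insertions <- list()
  for (k in seq_len(nrow(seeds$members))) {
    id <- seeds$members$id[k]
    if (id == seeds$master_id) {
      cols[[id]] <- mchars
      next
    }
    aln <- align_to_master(master$residues, seeds$members$residues[k],
                           matrix, gap_open, gap_extend)
    span <- if (aln$score > 0) aln$master_end - aln$master_start + 1L else 0L
    if (span < min_coverage * L) {
      excluded[[length(excluded) + 1L]] <- tibble::tibble(
        id = id, reason = sprintf("coverage %.2f < %.2f", span / L,
                                  min_coverage))
      next
    }
    row <- rep(NA_character_, L)
    row[aln$master_start:aln$master_end] <- "-"
    memchars <- strsplit(seeds$members$residues[k], "", fixed = TRUE)[[1]]
    row[aln$pairs$master_pos] <- memchars[aln$pairs$member_pos]
    cols[[id]] <- row
    n_ins <- (aln$member_end - aln$member_start + 1L) - nrow(aln$pairs)
    if (n_ins > 0L) {
      insertions[[length(insertions) + 1L]] <- tibble::tibble(
        id = id, n_inserted = n_ins)
    }
  }
  if (length(cols) == 0L) stop("degenerate family: no member passed coverage")
  ali <- do.call(cbind, cols)
  structure(list(
    master = master, ali = ali, member_ids = colnames(ali),
    excluded = if (length(excluded)) dplyr::bind_rows(excluded) else
      tibble::tibble(id = character(), reason = character()),
    insertions = if (length(insertions)) dplyr::bind_rows(insertions) else
      tibble::tibble(id = character(), n_inserted = integer())),
    class = "master_msa")
}

#' @export
print.master_msa <- function(x, ...) {
  cat("<master_msa> master ", x$master$id, ", ", nrow(x$ali),
      " column(s) x ", ncol(x$ali), " member(s)\n", sep = "")
  invisible(x)
}

#' Henikoff position-based sequence weights
#'
#' In each column a residue occurring in a column with `r` distinct
#' residue types, shared by `s` members, contributes `1/(r*s)` to the
#' weight of each of those members. A member's weight is the mean of its
#' contributions over the columns where it has a residue; weights are
#' normalized to sum to 1. Down-weights redundant subsets of near
#' identical sequences so they cannot dominate the profile.
#'
#' @param msa A `master_msa`.
#' @return Named numeric vector of member weights summing to 1.
#' @export
position_based_weights <- function(msa) {
  ali <- msa$ali
  n <- ncol(ali)
  if (n == 1L) return(stats::setNames(1, colnames(ali)))
  contrib <- matrix(NA_real_, nrow(ali), n, dimnames = dimnames(ali))
  for (i in seq_len(nrow(ali))) {
    row <- ali[i, ]
    isres <- !is.na(row) & row != "-"
    if (!any(isres)) next
    tab <- table(row[isres])
    r <- length(tab)
    contrib[i, isres] <- 1 / (r * as.numeric(tab[row[isres]]))
  }
  w <- colMeans(contrib, na.rm = TRUE)
  w[is.nan(w)] <- 0
  if (sum(w) == 0) w[] <- 1 / n
  w / sum(w)
}

#' Effective number of observations for pseudocount mixing
#'
#' The mean number of distinct residue types per column across the
#' alignment (columns with at least one residue), floored at 1. Drives
#' the data weight `alpha = N_c - 1` in the pseudocount mixture: a
#' single-sequence alignment carries no substitution information
#' (`alpha = 0`), a diverse one progressively more.
#'
#' @param msa A `master_msa`.
#' @param column Column index (the block here is the whole alignment, so
#'   every column returns the same value; the argument keeps the
#'   per-column contract and validates the index).
#' @return Real `>= 1`.
#' @export
effective_observations <- function(msa, column = 1L) {
  stopifnot(column >= 1L, column <= nrow(msa$ali))
  counts <- apply(msa$ali, 1, function(row) {
    isres <- !is.na(row) & row != "-"
    length(unique(row[isres]))
  })
  counts <- counts[counts > 0]
  if (length(counts) == 0L) return(1)
  max(1, mean(counts))
}

#' Pseudocount-mixed residue frequencies
#'
#' Altschul-style mixture of observed weighted frequencies `f` with
#' matrix-derived target frequencies
#' `g_a = sum_b f_b * Pr(a | b)` where
#' `Pr(a | b)` is proportional to `p_a exp(lambda * s_ab)` (normalized
#' over `a`):
#' \deqn{Q_a = \frac{\alpha f_a + \beta g_a}{\alpha + \beta}}
#'
#' @param observed 20-vector of observed frequencies summing to 1
#'   (matrix residue order).
#' @param matrix A `subst_matrix`.
#' @param alpha Data weight (`>= 0`), typically effective observations
#'   minus 1.
#' @param beta Pseudocount weight (`>= 0`).
#' @return 20-vector summing to 1; strictly positive whenever
#'   `beta > 0`.
#' @export
pseudo_frequencies <- function(observed, matrix, alpha, beta) {
  stopifnot(length(observed) == 20L, alpha >= 0, beta >= 0)
  if (alpha + beta == 0) stop("alpha + beta must be > 0")
  stopifnot(abs(sum(observed) - 1) < 1e-6)
  p <- matrix$background_freqs
  s20 <- matrix$scores[AA20, AA20]
  cond <- exp(matrix$ungapped_lambda * s20) * p  # cond[a, b] ~ p_a e^(l s)
  cond <- sweep(cond, 2, colSums(cond), "/")
  g <- as.numeric(cond %*% observed)
  q <- (alpha * observed + beta * g) / (alpha + beta)
  stats::setNames(q / sum(q), AA20)
}

#' Build a PSSM from a master-slave alignment
#'
#' Per master column: position-based weighted residue frequencies are
#' mixed with matrix-derived pseudocounts (`alpha = N_c - 1`, `beta`
#' fixed) and converted to integer log-odds
#' `s_a = round(log(Q_a / p_a) / scale)` (rounding half away from zero),
#' by default in half-bit units (`scale = ln 2 / 2`). Columns with no
#' aligned residue fall back to the substitution-matrix row of the
#' master residue and are flagged. The `X` column is fixed at -1.
#'
#' @param msa A `master_msa`.
#' @param matrix A `subst_matrix`.
#' @param beta Pseudocount weight (default 10, the classic constant).
#' @param scale Score unit in nats (default `log(2)/2`, half-bits).
#' @param gap_open,gap_extend Gap penalties recorded for downstream
#'   search.
#' @param gapped_K Karlin-Altschul K used for E-values when no
#'   calibration is run (default 0.041, the standard gapped BLOSUM62
#'   value).
#' @param family Family label; defaults to the master id.
#' @return Object of class `pssm`; see [read_pssm()] for fields.
#' @export
pssm_from_msa <- function(msa, matrix, beta = 10, scale = log(2) / 2,
                          gap_open = 11L, gap_extend = 1L,
                          gapped_K = 0.041, family = NULL) {
  stopifnot(inherits(msa, "master_msa"))
  if (is.null(family)) family <- msa$master$id
  L <- nrow(msa$ali)
  w <- position_based_weights(msa)
  n_eff <- effective_observations(msa, 1L)
  alpha <- n_eff - 1
  p <- matrix$background_freqs
  mchars <- strsplit(msa$master$residues, "", fixed = TRUE)[[1]]

  scores <- matrix(-1L, L, 21L, dimnames = list(NULL, AAX))
  freqs <- matrix(0, L, 20L, dimnames = list(NULL, AA20))
  flagged <- integer(0)
  for (i in seq_len(L)) {
    row <- msa$ali[i, ]
    isres <- !is.na(row) & row != "-" & row != "X"
    if (!any(isres)) {
      scores[i, ] <- matrix$scores[mchars[i], ]
      # background-composition placeholder keeps row sums defined
      freqs[i, ] <- p
      flagged <- c(flagged, i)
      next
    }
    wcov <- w[names(row)[isres]]
    f <- stats::setNames(numeric(20), AA20)
    for (a in unique(row[isres])) {
      f[a] <- sum(wcov[row[isres] == a])
    }
    f <- f / sum(f)
    q <- pseudo_frequencies(f, matrix, alpha, beta)
    freqs[i, ] <- f
    scores[i, AA20] <- as.integer(round_half_away(log(q / p) / scale))
  }
  structure(list(
    family = family, length = L, consensus = msa$master$residues,
    scores = scores, weighted_freqs = freqs, background_freqs = p,
    scale_lambda = scale, gapped_K = gapped_K,
    gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
    pseudocount_beta = beta, flagged_columns = flagged),
    class = "pssm")
}

#' Build a family PSSM straight from a seed set
#'
#' Convenience pipeline: [build_msa()] then [pssm_from_msa()].
#'
#' @inheritParams build_msa
#' @inheritParams pssm_from_msa
#' @return A `pssm`.
#' @export
build_family_pssm <- function(seeds, matrix, min_coverage = 0.5,
                              beta = 10, scale = log(2) / 2,
                              gap_open = 11L, gap_extend = 1L) {
  msa <- build_msa(seeds, matrix, min_coverage, gap_open, gap_extend)
  pssm_from_msa(msa, matrix, beta = beta, scale = scale,
                gap_open = gap_open, gap_extend = gap_extend,
                family = seeds$family)
}

#' @export
print.pssm <- function(x, ...) {
  cat("<pssm> ", x$family, ": ", x$length, " positions, half-bit scale ",
      sprintf("%.4f", x$scale_lambda), ", beta ", x$pseudocount_beta,
      "\n", sep = "")
  invisible(x)
}

#' Tidy a PSSM into long form
#'
#' @param x A `pssm`.
#' @param ... Unused.
#' @return Tibble with `position`, `consensus`, `residue`, `score`,
#'   `freq` (frequency `NA` for the X column).
#' @export
tidy.pssm <- function(x, ...) {
  cons <- strsplit(x$consensus, "", fixed = TRUE)[[1]]
  tibble::tibble(
    position = rep(seq_len(x$length), times = 21L),
    consensus = rep(cons, times = 21L),
    residue = rep(AAX, each = x$length),
    score = as.integer(x$scores),
    freq = c(as.numeric(x$weighted_freqs), rep(NA_real_, x$length)))
}

#' One-row PSSM summary
#'
#' @param x A `pssm`.
#' @param ... Unused.
#' @return One-row tibble: family, length, scale_lambda, gapped_K, gap
#'   penalties, pseudocount beta, number of fallback columns.
#' @export
glance.pssm <- function(x, ...) {
  tibble::tibble(family = x$family, length = x$length,
                 scale_lambda = x$scale_lambda, gapped_K = x$gapped_K,
                 gap_open = x$gap_open, gap_extend = x$gap_extend,
                 pseudocount_beta = x$pseudocount_beta,
                 n_fallback_columns = length(x$flagged_columns))
}

#' Heatmap of PSSM scores
#'
#' @param object A `pssm`.
#' @param ... Unused.
#' @return A ggplot object (position x residue score heatmap).
#' @export
autoplot.pssm <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$residue != "X", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$residue,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(title = paste0(object$family, " profile"),
                  x = "profile position", y = NULL,
                  fill = "half-bit\nscore") +
    ggplot2::theme_minimal()
}

#' Write a PSSM to its ASCII interchange format
#'
#' Header lines `# family:`, `# length:`, `# lambda:`, `# K:`,
#' `# gap:<open>,<extend>`, `# beta:`, `# background:` followed by one
#' tab-separated row per position: index, consensus residue, 20 integer
#' scores, 20 frequencies (4 decimals). Doubles in the header are
#' printed at full precision so numeric fields round-trip bit-exactly;
#' frequencies round-trip at the printed 4-decimal precision.
#'
#' @param pssm A `pssm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  cons <- strsplit(pssm$consensus, "", fixed = TRUE)[[1]]
  hdr <- c(
    paste0("# family:", pssm$family),
    paste0("# length:", pssm$length),
    paste0("# lambda:", sprintf("%.17g", pssm$scale_lambda)),
    paste0("# K:", sprintf("%.17g", pssm$gapped_K)),
    paste0("# gap:", pssm$gap_open, ",", pssm$gap_extend),
    paste0("# beta:", sprintf("%.17g", pssm$pseudocount_beta)),
    paste0("# background:",
           paste(sprintf("%.17g", pssm$background_freqs), collapse = ",")))
  rows <- vapply(seq_len(pssm$length), function(i) {
    paste(c(i, cons[i], pssm$scores[i, AA20],
            sprintf("%.4f", pssm$weighted_freqs[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a PSSM from the ASCII interchange format
#'
#' @param path Path written by [write_pssm()].
#' @return A `pssm` object.
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln) != 1L) stop("PSSM parse error: missing header '", key, "'")
    sub(paste0("^# ", key, ":"), "", ln)
  }
  fam <- get("family")
  L <- as.integer(get("length"))
  lambda <- as.numeric(get("lambda"))
  K <- as.numeric(get("K"))
  gaps <- as.integer(strsplit(get("gap"), ",")[[1]])
  beta <- as.numeric(get("beta"))
  bg <- as.numeric(strsplit(get("background"), ",")[[1]])
  if (length(bg) != 20L) stop("PSSM parse error: background must have 20 values")
  names(bg) <- AA20

  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) != L) {
    stop("PSSM parse error: header length ", L, " but ", length(body),
         " data rows")
  }
  scores <- matrix(-1L, L, 21L, dimnames = list(NULL, AAX))
  freqs <- matrix(0, L, 20L, dimnames = list(NULL, AA20))
  cons <- character(L)
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 42L) {
      stop("PSSM parse error at data row ", i, ": expected 42 fields")
    }
    cons[i] <- parts[2]
    scores[i, AA20] <- as.integer(parts[3:22])
    freqs[i, ] <- as.numeric(parts[23:42])
  }
  structure(list(
    family = fam, length = L, consensus = paste(cons, collapse = ""),
    scores = scores, weighted_freqs = freqs, background_freqs = bg,
    scale_lambda = lambda, gapped_K = K,
    gap_open = gaps[1], gap_extend = gaps[2], pseudocount_beta = beta,
    flagged_columns = integer(0)),
    class = "pssm")
}
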