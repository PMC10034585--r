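#' Best ungapped alignment of a sequence against a homopolymer
#'
#' Scores every position of `seq` against an infinite homopolymer of
#' `residue` using the substitution matrix and returns the maximal
#' scoring contiguous segment (Kadane scan). This is the detection
#' primitive behind compositional-bias masking: a run enriched in one
#' residue type accumulates positive self-substitution score.
#'
#' @param seq Residue string (or a single-row sequence tibble).
#' @param residue One of the 20 standard amino acids.
#' @param matrix A `subst_matrix`.
#' @return A list with `score` (integer; 0 when no positive segment
#'   exists), `start`, `end` (1-based inclusive; `NA` when score is 0).
#'   Ties resolve to the leftmost maximal segment.
#' @export
homopolymer_bias_score <- function(seq, residue, matrix) {
  if (is.data.frame(seq)) seq <- seq$residues[[1]]
  stopifnot(nzchar(seq), residue %in% AA20)
  s <- unname(matrix$scores[residue, aa_index(seq)])
  # leftmost maximal segment of maximal sum, via prefix sums:
  # segment (i, j] scores P[j] - P[i]; ties take the first maximal end
  # and the earliest start achieving it
  P <- c(0L, cumsum(s))
  prevmin <- cummin(P)[-length(P)]
  gain <- P[-1] - prevmin
  best <- max(gain)
  if (best <= 0L) {
    return(list(score = 0L, start = NA_integer_, end = NA_integer_))
  }
  j <- which.max(gain)
  i <- which(P[seq_len(j)] == prevmin[j])[1]
  list(score = as.integer(best), start = i, end = j)
}

#' Mask compositionally biased regions in a protein sequence
#'
#' Iterative hard-masking of low-complexity / repeat-biased runs: at each
#' round the homopolymer bias score is computed for all 20 residue types;
#' if the best score exceeds `threshold`, occurrences of that residue
#' type inside its maximal segment are replaced by `X`, the segment is
#' recorded, and the scan repeats on the masked sequence. Iteration stops
#' when no residue type scores above the threshold. Ties between residue
#' types at equal score resolve alphabetically.
#'
#' @param seq Residue string or single-row sequence tibble.
#' @param threshold Positive integer score threshold (default 15, the
#'   setting used for nucleoporin screening).
#' @param matrix A `subst_matrix`; defaults to bundled BLOSUM62.
#' @return An object of class `masked_seq`: list with `source`, `masked`
#'   (same length, biased positions replaced by X), `segments` (tibble
#'   `residue_type`, `start`, `end`, `score`), `threshold`.
#' @examples
#' m <- load_substitution_matrix("BLOSUM62")
#' mask_compositional_bias(paste0("MKVL", strrep("Q", 30), "WEDA"), matrix = m)
#' @export
mask_compositional_bias <- function(seq, threshold = 15L, matrix = NULL) {
  if (is.null(matrix)) matrix <- load_substitution_matrix("BLOSUM62")
  if (is.data.frame(seq)) seq <- seq$residues[[1]]
  stopifnot(threshold > 0)
  source <- toupper(seq)
  cur <- source
  segs <- list()
  repeat {
    scans <- lapply(AA20, function(a) homopolymer_bias_score(cur, a, matrix))
    scores <- vapply(scans, `[[`, integer(1), "score")
    # deterministic: highest score, alphabetical residue on ties
    best_score <- max(scores)
    if (best_score <= threshold) break
    cand <- sort(AA20[scores == best_score])[1]
    hit <- scans[[match(cand, AA20)]]
    chars <- strsplit(cur, "", fixed = TRUE)[[1]]
    idx <- hit$start:hit$end
    chars[idx][chars[idx] == cand] <- "X"
    cur <- paste(chars, collapse = "")
    segs[[length(segs) + 1L]] <- tibble::tibble(
      residue_type = cand, start = hit$start, end = hit$end,
      score = hit$score)
  }
  segments <- if (length(segs)) dplyr::bind_rows(segs) else
    tibble::tibble(residue_type = character(), start = integer(),
                   end = integer(), score = integer())
  structure(list(source = source, masked = cur, segments = segments,
                 threshold = as.integer(threshold)),
            class = "masked_seq")
}

#' @export
print.masked_seq <- function(x, ...) {
  cat("<masked_seq> ", nchar(x$source), " residues, ",
      nrow(x$segments), " biased segment(s), threshold ", x$threshold,
      "\n", sep = "")
  invisible(x)
}

#' Mask every sequence in a collection
#'
#' Data-frame-first wrapper over [mask_compositional_bias()]: returns the
#' sequence tibble with residues hard-masked and a `bias_segments`
#' attribute... segments are returned as an ordinary column-bound tibble
#' via [bias_segments()].
#'
#' @param seqs Sequence tibble.
#' @inheritParams mask_compositional_bias
#' @return The input tibble with `residues` masked plus a list-column
#'   `bias_segments` of per-sequence segment tibbles.
#' @export
mask_sequences <- function(seqs, threshold = 15L, matrix = NULL) {
  if (is.null(matrix)) matrix <- load_substitution_matrix("BLOSUM62")
  seqs <- as_seq_tbl(seqs)
  masked <- lapply(seqs$residues, mask_compositional_bias,
                   threshold = threshold, matrix = matrix)
  seqs$residues <- vapply(masked, `[[`, character(1), "masked")
  seqs$bias_segments <- lapply(masked, `[[`, "segments")
  seqs
}

#' Extract bias segments from a masked collection as one tidy table
#'
#' @param masked_seqs Output of [mask_sequences()].
#' @return Tibble with `id`, `residue_type`, `start`, `end`, `score`.
#' @export
bias_segments <- function(masked_seqs) {
  stopifnot("bias_segments" %in% names(masked_seqs))
  out <- masked_seqs |>
    dplyr::select(dplyr::all_of(c("id", "bias_segments"))) |>
    tidyr::unnest("bias_segments")
  out
}
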