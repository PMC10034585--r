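#' Build and validate an expected-composition gold standard
#'
#' The species-by-family presence/absence table the evaluation is scored
#' against: each expected-true cell names the true protein id(s) in that
#' species' proteome; expected-absent cells have no truth ids. The
#' classic design is 15 species x 36 families with 134 literature-absent
#' cells, leaving 406 evaluated entries.
#'
#' @param cells Tibble with columns `species`, `family`,
#'   `expected` (logical or 0/1) and `truth_ids` (comma-separated string
#'   or list-column of character vectors; required exactly where
#'   `expected` is true).
#' @return An `expected_composition` object (validated tibble).
#' @export
expected_composition <- function(cells) {
  stopifnot(all(c("species", "family", "expected") %in% names(cells)))
  cells <- tibble::as_tibble(cells)
  cells$expected <- as.logical(cells$expected)
  if (!"truth_ids" %in% names(cells)) cells$truth_ids <- list(character(0))
  if (is.character(cells$truth_ids)) {
    cells$truth_ids <- lapply(strsplit(cells$truth_ids, ","),
                              function(x) x[nzchar(x)])
  }
  if (anyDuplicated(cells[, c("species", "family")])) {
    stop("duplicate (species, family) cells")
  }
  n_truth <- lengths(cells$truth_ids)
  if (any(cells$expected & n_truth == 0L)) {
    stop("expected-true cells without truth ids")
  }
  if (any(!cells$expected & n_truth > 0L)) {
    stop("expected-absent cells must not carry truth ids")
  }
  n_sp <- length(unique(cells$species))
  n_fam <- length(unique(cells$family))
  if (nrow(cells) != n_sp * n_fam) {
    stop("expected composition must cover the full species x family grid: ",
         n_sp, " x ", n_fam, " != ", nrow(cells))
  }
  structure(cells, class = c("expected_composition", class(cells)))
}

#' Counts summary of an expected-composition table
#'
#' @param x An `expected_composition`.
#' @param ... Unused.
#' @return One-row tibble: `n_species`, `n_families`, `n_cells`,
#'   `n_expected` (evaluated entries), `n_absent`.
#' @export
glance.expected_composition <- function(x, ...) {
  tibble::tibble(
    n_species = length(unique(x$species)),
    n_families = length(unique(x$family)),
    n_cells = nrow(x),
    n_expected = sum(x$expected),
    n_absent = sum(!x$expected))
}

#' Read an expected-composition TSV
#'
#' Columns `species`, `family`, `expected` (0/1), `truth_ids`
#' (comma-separated, empty for absent cells).
#'
#' @param path Path to the TSV.
#' @return An `expected_composition`.
#' @export
read_expected_composition <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "integer", "character"))
  expected_composition(df)
}

#' Write an expected-composition table as TSV
#'
#' @param ec An `expected_composition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expected_composition <- function(ec, path) {
  df <- data.frame(
    species = ec$species, family = ec$family,
    expected = as.integer(ec$expected),
    truth_ids = vapply(ec$truth_ids, paste, "", collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a HMMER3 tblout file into a hit table
#'
#' Parses the whitespace-separated per-target table written by
#' `hmmsearch --tblout` (with or without the heuristic-filter-disabling
#' `--max` option; the layout is identical), keeping the target id, the
#' full-sequence E-value and score, sorted ascending by E-value so ranks
#' are directly comparable with native hit tables.
#'
#' @param path Path to a tblout file.
#' @return A `hit_tbl` with `family` (query name), `subject_id`,
#'   `evalue`, `bit_score`; alignment-coordinate columns are `NA` (tblout
#'   does not carry them).
#' @export
read_hmmer_tblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(new_hit_tbl(empty_hit_tbl()))
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) < 18L) {
      stop("tblout parse error at data line ", i,
           ": expected >= 18 fields, got ", length(parts))
    }
    ev <- suppressWarnings(as.numeric(parts[5]))
    sc <- suppressWarnings(as.numeric(parts[6]))
    if (is.na(ev) || is.na(sc)) {
      stop("tblout parse error at data line ", i,
           ": non-numeric E-value/score")
    }
    tibble::tibble(
      family = parts[3], subject_id = parts[1],
      pident = NA_real_, length = NA_integer_, mismatch = NA_integer_,
      gapopen = NA_integer_, qstart = NA_integer_, qend = NA_integer_,
      sstart = NA_integer_, send = NA_integer_,
      evalue = ev, bit_score = sc)
  })
  tab <- dplyr::bind_rows(rows)
  tab <- tab[order(tab$evalue, -tab$bit_score, tab$subject_id), ]
  new_hit_tbl(tab, family = tab$family[1])
}

#' Rank of the true protein in a hit list
#'
#' The top-hit detection criterion: a family member counts as detected
#' in a species only when the true protein ranks first in the profile's
#' hit list. Lower ranks are reported but scored as misses.
#'
#' @param hits A `hit_tbl`, sorted by ascending E-value.
#' @param truth_ids Character vector of acceptable true protein ids
#'   (several for multi-copy genes; the best-ranked one counts).
#' @return One-row tibble (`rank`, `detected`, `evalue_of_true`); `rank`
#'   is `NA` when no truth id appears in the reported list.
#' @export
rank_true_hits <- function(hits, truth_ids) {
  if (length(truth_ids) == 0L) {
    stop("empty truth_ids: expected-absent cells are never ranked")
  }
  pos <- which(hits$subject_id %in% truth_ids)
  if (length(pos) == 0L) {
    return(tibble::tibble(rank = NA_integer_, detected = FALSE,
                          evalue_of_true = NA_real_))
  }
  r <- min(pos)
  tibble::tibble(rank = as.integer(r), detected = r == 1L,
                 evalue_of_true = hits$evalue[r])
}

#' Confusion counts for family detection
#'
#' Scores detection records against an expected-composition table:
#' TP = expected-true cells whose true protein ranked first, FN = the
#' remaining expected-true cells, FP = expected-absent cells whose hit
#' list contains any call at `E <= fp_evalue`, TN = the remaining absent
#' cells.
#'
#' @param ec An `expected_composition`.
#' @param records Tibble with one row per expected-true cell: `species`,
#'   `family`, `detected` (and usually `rank`).
#' @param absent_calls Optional tibble of the best call per
#'   expected-absent cell: `species`, `family`, `min_evalue` (`NA` or
#'   `Inf` when no hit was returned). Missing rows count as no-call.
#' @param fp_evalue E-value at or below which a call in an absent cell
#'   counts as a false positive.
#' @return A `confusion_counts` object (fields `TP`, `FN`, `FP`, `TN`).
#' @export
confusion <- function(ec, records, absent_calls = NULL,
                      fp_evalue = 1e-5) {
  stopifnot(inherits(ec, "expected_composition"))
  exp_cells <- ec[ec$expected, c("species", "family")]
  keyed <- dplyr::left_join(exp_cells, records,
                            by = c("species", "family"))
  if (anyNA(keyed$detected)) {
    missing <- keyed[is.na(keyed$detected), c("species", "family")]
    stop("missing detection records for ", nrow(missing), " cell(s): ",
         paste(utils::head(paste(missing$species, missing$family, sep = "/"),
                           5), collapse = ", "))
  }
  tp <- sum(keyed$detected)
  fn <- sum(!keyed$detected)

  abs_cells <- ec[!ec$expected, c("species", "family")]
  fp <- 0L
  if (nrow(abs_cells) > 0L && !is.null(absent_calls)) {
    j <- dplyr::left_join(abs_cells, absent_calls,
                          by = c("species", "family"))
    fp <- sum(!is.na(j$min_evalue) & j$min_evalue <= fp_evalue)
  }
  confusion_counts(tp, fn, fp, nrow(abs_cells) - fp)
}

#' Construct confusion counts directly
#'
#' @param TP,FN,FP,TN Nonnegative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TP, FN, FP = 0L, TN = 0L) {
  stopifnot(TP >= 0, FN >= 0, FP >= 0, TN >= 0)
  structure(list(TP = as.integer(TP), FN = as.integer(FN),
                 FP = as.integer(FP), TN = as.integer(TN)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP", x$TP, "FN", x$FN, "FP", x$FP, "TN", x$TN,
      sprintf("| TPR %.1f%%, FNR %.1f%%\n", tpr(x), fnr(x)))
  invisible(x)
}

#' True positive rate (percent, one decimal)
#'
#' `TPR = 100 * TP / (TP + FN)`, rounded half-up to one decimal; the
#' headline sensitivity of top-hit detection.
#'
#' @param c A `confusion_counts`.
#' @return Percentage, one decimal.
#' @export
tpr <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$TP + c$FN == 0L) stop("TPR undefined: TP + FN = 0")
  round_half_up(100 * c$TP / (c$TP + c$FN), 1)
}

#' False negative rate (percent, one decimal)
#'
#' @param c A `confusion_counts`.
#' @return `100 * FN / (TP + FN)`, rounded half-up to one decimal.
#' @export
fnr <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$TP + c$FN == 0L) stop("FNR undefined: TP + FN = 0")
  round_half_up(100 * c$FN / (c$TP + c$FN), 1)
}

#' TPR difference between two methods
#'
#' @param a,b `confusion_counts` for the two methods.
#' @return `tpr(a) - tpr(b)` in percentage points, one decimal.
#' @export
compare_methods <- function(a, b) {
  round_half_up(tpr(a) - tpr(b), 1)
}

#' Tidy confusion counts
#'
#' @param x A `confusion_counts`.
#' @param ... Unused.
#' @return Long tibble with `cell` (TP/FN/FP/TN) and `count`.
#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble::tibble(cell = c("TP", "FN", "FP", "TN"),
                 count = c(x$TP, x$FN, x$FP, x$TN))
}

#' One-row confusion summary with rates
#'
#' @param x A `confusion_counts`.
#' @param ... Unused.
#' @return One-row tibble: counts, `tpr`, `fnr`, `n_evaluated`.
#' @export
glance.confusion_counts <- function(x, ...) {
  tibble::tibble(TP = x$TP, FN = x$FN, FP = x$FP, TN = x$TN,
                 tpr = tpr(x), fnr = fnr(x),
                 n_evaluated = x$TP + x$FN)
}

#' Species-by-family rank matrix report
#'
#' The rank-of-true-hit grid: one row per species, one column per
#' family, each evaluated cell showing the rank of the true protein in
#' that profile's hit list ("-" when absent from the reported list, "."
#' for cells not expected). Cells with rank different from 1 are the
#' red-flag entries.
#'
#' @param records Detection-record tibble (`species`, `family`, `rank`,
#'   `detected`).
#' @param ec An `expected_composition`.
#' @return A `rank_matrix`: wide tibble (first column `species`) with a
#'   `summary` attribute (one-row tibble of detected / lower-ranked /
#'   not-detected counts).
#' @export
rank_matrix_report <- function(records, ec) {
  stopifnot(inherits(ec, "expected_composition"))
  if (nrow(ec) == 0L) {
    out <- tibble::tibble(species = character())
    attr(out, "summary") <- tibble::tibble(
      detected = 0L, ranked_lower = 0L, not_detected = 0L)
    class(out) <- c("rank_matrix", class(out))
    return(out)
  }
  grid <- ec[, c("species", "family", "expected")]
  grid <- dplyr::left_join(grid, records[, c("species", "family", "rank")],
                           by = c("species", "family"))
  grid$cell <- dplyr::case_when(
    !grid$expected ~ ".",
    is.na(grid$rank) ~ "-",
    TRUE ~ as.character(grid$rank))
  wide <- tidyr::pivot_wider(grid[, c("species", "family", "cell")],
                             names_from = "family", values_from = "cell")
  eval_rows <- grid[grid$expected, ]
  smry <- tibble::tibble(
    detected = sum(!is.na(eval_rows$rank) & eval_rows$rank == 1L),
    ranked_lower = sum(!is.na(eval_rows$rank) & eval_rows$rank > 1L),
    not_detected = sum(is.na(eval_rows$rank)))
  attr(wide, "summary") <- smry
  class(wide) <- c("rank_matrix", class(wide))
  wide
}

#' @export
print.rank_matrix <- function(x, ...) {
  NextMethod()
  s <- attr(x, "summary")
  cat(sprintf("summary: %d detected, %d ranked lower, %d not detected\n",
              s$detected, s$ranked_lower, s$not_detected))
  invisible(x)
}

#' Tile plot of a rank matrix
#'
#' @param object A `rank_matrix`.
#' @param ... Unused.
#' @return A ggplot object; rank-1 cells in green, lower ranks amber,
#'   misses red, not-expected cells grey.
#' @export
autoplot.rank_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"species",
                              names_to = "family", values_to = "cell")
  long$status <- dplyr::case_when(
    long$cell == "." ~ "not expected",
    long$cell == "-" ~ "not detected",
    long$cell == "1" ~ "top hit",
    TRUE ~ "ranked lower")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$family, y = .data$species,
                                     fill = .data$status)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$cell), size = 2.5) +
    ggplot2::scale_fill_manual(values = c(
      "top hit" = "#66c2a5", "ranked lower" = "#fdae61",
      "not detected" = "#d53e4f", "not expected" = "grey85")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
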