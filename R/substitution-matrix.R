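#' Load a substitution matrix with Karlin-Altschul statistics
#'
#' Loads either the bundled BLOSUM62 table or any NCBI-format matrix file
#' (whitespace-separated, first row/column residue letters, `#` comments)
#' and attaches the pieces score statistics need: background residue
#' frequencies (Robinson-Robinson set), the ungapped Karlin-Altschul
#' `lambda` solved numerically from
#' \deqn{\sum_a \sum_b p_a p_b e^{\lambda s_{ab}} = 1}
#' and the ungapped `K`. Scores are extended to a 21st `X` row/column
#' fixed at -1 so masked residues never contribute positive signal.
#'
#' @param name_or_path `"BLOSUM62"` or a path to an NCBI-format matrix
#'   file.
#' @param background Optional 20-vector of background frequencies in the
#'   matrix residue order; defaults to the Robinson-Robinson frequencies
#'   (normalized to sum exactly 1).
#' @param K Ungapped Karlin-Altschul K; default 0.134 (the standard
#'   ungapped BLOSUM62 value), used when no calibration is available.
#' @return An object of class `subst_matrix`: list with `name`, `scores`
#'   (21x21 integer, dimnames A..V,X), `background_freqs` (named
#'   20-vector), `ungapped_lambda`, `ungapped_K`.
#' @examples
#' m <- load_substitution_matrix("BLOSUM62")
#' m$scores["W", "W"]   # 11
#' m$ungapped_lambda    # ~0.3176
#' @export
load_substitution_matrix <- function(name_or_path = "BLOSUM62",
                                     background = NULL, K = 0.134) {
  if (identical(name_or_path, "BLOSUM62")) {
    path <- system.file("extdata", "BLOSUM62", package = "profscan")
    name <- "BLOSUM62"
  } else {
    path <- name_or_path
    name <- basename(path)
  }
  if (!file.exists(path)) stop("matrix file not found: ", path)

  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  if (length(lines) < 2L) stop("malformed matrix file: no data rows")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(seq_along(lines)[-1], function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != length(header) + 1L) {
      stop("matrix parse error at line ", which(keep)[i],
           ": expected ", length(header) + 1L, " fields, got ", length(parts))
    }
    parts
  })
  letters_row <- vapply(rows, `[`, "", 1L)
  vals <- suppressWarnings(
    t(vapply(rows, function(p) as.numeric(p[-1]), numeric(length(header)))))
  if (anyNA(vals)) stop("matrix parse error: non-numeric score entry")
  dimnames(vals) <- list(letters_row, header)

  present <- intersect(AA20, intersect(rownames(vals), colnames(vals)))
  if (length(present) != 20L) {
    stop("matrix file must cover all 20 standard amino acids")
  }
  m20 <- vals[AA20, AA20]
  if (any(m20 != t(m20))) stop("asymmetric substitution matrix")
  if (any(m20 != round(m20))) stop("non-integer scores in matrix")

  scores <- matrix(-1L, 21L, 21L, dimnames = list(AAX, AAX))
  scores[AA20, AA20] <- as.integer(m20)

  if (is.null(background)) background <- robinson_frequencies()
  stopifnot(length(background) == 20L, all(background > 0))
  background <- background / sum(background)
  names(background) <- AA20

  lambda <- solve_matrix_lambda(m20, background)

  structure(
    list(name = name, scores = scores, background_freqs = background,
         ungapped_lambda = lambda, ungapped_K = K),
    class = "subst_matrix")
}

# Robinson & Robinson (1991) amino-acid frequencies, NCBI constants.
robinson_frequencies <- function() {
  f <- c(A = 78.05, R = 51.29, N = 44.87, D = 53.64, C = 19.25,
         Q = 42.64, E = 62.95, G = 73.77, H = 21.99, I = 51.42,
         L = 90.19, K = 57.44, M = 22.43, F = 38.56, P = 52.03,
         S = 71.20, T = 58.41, W = 13.30, Y = 32.04, V = 64.41) / 1000
  f / sum(f)
}

# Unique positive root of sum_ab p_a p_b exp(lambda * s_ab) = 1.
solve_matrix_lambda <- function(scores20, p) {
  pp <- outer(p, p)
  f <- function(l) sum(pp * exp(l * scores20)) - 1
  upper <- 0.5
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(1e-6, upper), tol = 1e-12)$root
}

#' @export
print.subst_matrix <- function(x, ...) {
  cat("<subst_matrix>", x$name,
      sprintf("| ungapped lambda %.4f, K %.3f\n",
              x$ungapped_lambda, x$ungapped_K))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a substitution matrix into long form
#'
#' @param x A `subst_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `a`, `b`, `score`.
#' @export
tidy.subst_matrix <- function(x, ...) {
  tibble::tibble(
    a = rep(rownames(x$scores), times = ncol(x$scores)),
    b = rep(colnames(x$scores), each = nrow(x$scores)),
    score = as.integer(x$scores))
}
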