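#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a sequence tibble, the tabular sequence
#' collection used throughout the package. The header token before the
#' first whitespace becomes the record `id`, the remainder the
#' `description`. Residues are uppercased and `*` stop characters are
#' stripped. The ambiguity codes B, Z, J, U and O are mapped to `X` with
#' a warning so that downstream scoring stays defined; records containing
#' any other illegal character (digits, punctuation) are rejected with a
#' warning and dropped.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `residues`
#'   (uppercase, alphabet = 20 standard amino acids plus `X`).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 a seed", "MKVLAW"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    warning("empty FASTA file: ", path)
    return(tibble::tibble(id = character(), description = character(),
                          residues = character()))
  }
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- unname(toupper(as.character(raw)))
  seqs <- gsub("*", "", seqs, fixed = TRUE)

  n_ambig <- 0L
  for (code in AMBIG_TO_X) {
    hit <- grepl(code, seqs, fixed = TRUE)
    n_ambig <- n_ambig + sum(hit)
    seqs[hit] <- gsub(code, "X", seqs[hit], fixed = TRUE)
  }
  if (n_ambig > 0L) {
    warning(n_ambig, " record(s) contained ambiguity codes (",
            paste(AMBIG_TO_X, collapse = "/"), "); mapped to X")
  }

  legal <- grepl(paste0("^[", paste(AAX, collapse = ""), "]+$"), seqs)
  if (any(!legal)) {
    warning("rejected ", sum(!legal),
            " record(s) with illegal residue characters: ",
            paste(utils::head(ids[!legal], 5), collapse = ", "))
  }
  keep <- legal & nzchar(seqs)
  if (any(legal & !nzchar(seqs))) {
    warning("rejected ", sum(legal & !nzchar(seqs)), " empty record(s)")
  }
  tibble::tibble(id = ids[keep], description = desc[keep],
                 residues = seqs[keep])
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Sequence tibble (columns `id`, `residues`, optionally
#'   `description`).
#' @param path Output path.
#' @param line_width Residues per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, line_width = 60L) {
  seqs <- as_seq_tbl(seqs)
  if (anyDuplicated(seqs$id)) {
    stop("duplicate sequence ids: ",
         paste(unique(seqs$id[duplicated(seqs$id)]), collapse = ", "))
  }
  set <- Biostrings::BStringSet(seqs$residues)
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  names(set) <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  Biostrings::writeXStringSet(set, path, width = line_width)
  invisible(path)
}

#' Coerce and validate a sequence table
#'
#' Checks the sequence-tibble contract: non-empty uppercase residues over
#' the 20-AA + X alphabet, whitespace-free unique-within-collection ids.
#'
#' @param x A data frame with at least `id` and `residues` columns.
#' @return A validated tibble (with a `description` column added if
#'   missing).
#' @export
as_seq_tbl <- function(x) {
  stopifnot(is.data.frame(x), all(c("id", "residues") %in% names(x)))
  x <- tibble::as_tibble(x)
  if (!"description" %in% names(x)) x$description <- ""
  if (any(grepl("\\s", x$id))) stop("sequence ids must not contain whitespace")
  x$residues <- toupper(x$residues)
  ok <- grepl(paste0("^[", paste(AAX, collapse = ""), "]+$"), x$residues)
  if (!all(ok)) {
    stop("invalid residues in: ", paste(utils::head(x$id[!ok], 5), collapse = ", "))
  }
  x
}
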