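# Internal residue alphabet: the 20 standard amino acids in NCBI matrix
# order, plus X (masked/unknown) as a 21st code. All score tables are
# 21x21 with the X row/column held constant.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
          "P","S","T","W","Y","V")
AAX <- c(AA20, "X")

# ambiguity codes degraded to X on input (B/Z = acid/amide ambiguity,
# J = I/L, U/O = non-standard translated residues)
AMBIG_TO_X <- c("B", "Z", "J", "U", "O")

#' @keywords internal
aa_index <- function(residues) {
  idx <- match(strsplit(residues, "", fixed = TRUE)[[1]], AAX)
  if (anyNA(idx)) {
    stop("sequence contains characters outside the 20-AA + X alphabet")
  }
  idx
}

#' @keywords internal
aa_string <- function(idx) paste(AAX[idx], collapse = "")

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# round half away from zero, used for integer log-odds scores
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
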