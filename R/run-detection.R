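#' Run the full detection protocol on a benchmark
#'
#' The evaluation pipeline applied to a synthetic benchmark: build one
#' PSSM per family from its training seeds, optionally hard-mask every
#' proteome (threshold-15 compositional-bias masking), scan each
#' proteome with each family profile (best HSP per subject, hit list
#' capped at 20, composition-based statistics on by default), rank the
#' true protein in every expected-true cell, and collect the best call
#' in every expected-absent cell for false-positive scoring.
#'
#' @param bench A `synthetic_benchmark` (or any list with `proteomes`,
#'   `families`, `expected` of the same shape).
#' @param cbs Composition-based statistics toggle.
#' @param mask Mask proteomes before scanning.
#' @param mask_threshold Bias-masking threshold.
#' @param evalue_cutoff,max_target_sequences Hit-list controls.
#' @param fp_evalue False-positive E-value criterion for absent cells.
#' @param matrix A `subst_matrix`; defaults to bundled BLOSUM62.
#' @return List: `records` (tibble species/family/rank/detected/
#'   evalue_of_true), `absent_calls` (species/family/min_evalue),
#'   `confusion` (a `confusion_counts`), `rank_matrix`, and `pssms`.
#' @export
run_detection <- function(bench, cbs = TRUE, mask = FALSE,
                          mask_threshold = 15L, evalue_cutoff = 10,
                          max_target_sequences = 20L, fp_evalue = 1e-5,
                          matrix = NULL) {
  if (is.null(matrix)) matrix <- load_substitution_matrix("BLOSUM62")
  ec <- bench$expected
  pssms <- lapply(bench$families, build_family_pssm, matrix = matrix)

  proteomes <- bench$proteomes
  if (mask) {
    proteomes <- lapply(proteomes, function(db) {
      m <- mask_sequences(db, threshold = mask_threshold, matrix = matrix)
      m$bias_segments <- NULL
      m
    })
  }

  records <- list()
  absent_calls <- list()
  for (sp in names(proteomes)) {
    db <- proteomes[[sp]]
    for (fam in names(pssms)) {
      cell <- ec[ec$species == sp & ec$family == fam, ]
      if (nrow(cell) == 0L) next
      hits <- search_proteome(pssms[[fam]], db,
                              evalue_cutoff = evalue_cutoff,
                              max_target_sequences = max_target_sequences,
                              cbs = cbs, proteome_id = sp)
      if (cell$expected) {
        rec <- rank_true_hits(hits, cell$truth_ids[[1]])
        rec$species <- sp
        rec$family <- fam
        records[[paste(sp, fam)]] <- rec
      } else {
        absent_calls[[paste(sp, fam)]] <- tibble::tibble(
          species = sp, family = fam,
          min_evalue = if (nrow(hits)) min(hits$evalue) else NA_real_)
      }
    }
  }
  records <- dplyr::bind_rows(records)
  absent_calls <- if (length(absent_calls)) dplyr::bind_rows(absent_calls)
    else tibble::tibble(species = character(), family = character(),
                        min_evalue = numeric())
  conf <- confusion(ec, records, absent_calls, fp_evalue = fp_evalue)
  list(records = records, absent_calls = absent_calls, confusion = conf,
       rank_matrix = rank_matrix_report(records, ec), pssms = pssms)
}
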