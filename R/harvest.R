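#' Filter a database down to complete sequences
#'
#' Mirrors the "NOT fragment NOT partial" query used when harvesting
#' homologs: drops records whose description contains a blacklisted
#' keyword (case-insensitive) or whose length falls below a fraction of
#' the master length, so truncated entries never dilute profile columns.
#'
#' @param db Sequence tibble.
#' @param master_length Master sequence length used for the length rule.
#' @param min_len_fraction Minimum length as a fraction of
#'   `master_length`.
#' @param keyword_blacklist Description keywords that mark incomplete
#'   records.
#' @return Filtered tibble with a `removed` attribute (tibble id/reason).
#' @export
prefilter_complete <- function(db, master_length,
                               min_len_fraction = 0.5,
                               keyword_blacklist = c("fragment", "partial")) {
  db <- as_seq_tbl(db)
  desc <- tolower(db$description)
  kw_hit <- Reduce(`|`, lapply(keyword_blacklist,
                               function(k) grepl(k, desc, fixed = TRUE)),
                   accumulate = FALSE)
  if (is.null(kw_hit)) kw_hit <- rep(FALSE, nrow(db))
  short <- nchar(db$residues) < min_len_fraction * master_length
  removed <- tibble::tibble(
    id = db$id[kw_hit | short],
    reason = ifelse(kw_hit[kw_hit | short], "blacklisted keyword",
                    "below length fraction"))
  out <- db[!(kw_hit | short), ]
  attr(out, "removed") <- removed
  out
}

#' Reciprocal validation of a candidate hit
#'
#' Extracts the matching region of a candidate (the HSP's subject
#' interval), aligns it locally against every sequence of a labeled
#' reference set, and accepts the candidate only when the best-scoring
#' reference sequence belongs to the harvesting family — the reverse
#' search used to ascertain that a new hit really is a family member.
#'
#' @param candidate_hsp One-row hit tibble (needs `family`, `sstart`,
#'   `send`).
#' @param candidate Residue string or single-row sequence tibble.
#' @param seed_db Sequence tibble with a `family` column (reference
#'   seeds across families).
#' @param matrix A `subst_matrix`.
#' @return `TRUE`/`FALSE`.
#' @export
reciprocal_check <- function(candidate_hsp, candidate, seed_db, matrix) {
  if (is.data.frame(candidate)) candidate <- candidate$residues[[1]]
  stopifnot("family" %in% names(seed_db))
  region <- substr(candidate, candidate_hsp$sstart, candidate_hsp$send)
  if (!nzchar(region)) {
    warning("empty candidate region")
    return(FALSE)
  }
  if (grepl("^X+$", region)) return(FALSE)
  scores <- vapply(seq_len(nrow(seed_db)), function(k) {
    align_to_master(region, seed_db$residues[k], matrix)$score
  }, numeric(1))
  if (max(scores) <= 0) return(FALSE)
  best <- which(scores == max(scores))[1]
  identical(seed_db$family[best], candidate_hsp$family)
}

#' Iterative family delineation against a local database
#'
#' The automatable core of profile-based homolog harvesting: build a
#' PSSM from the current members (masked at threshold 15 so biased
#' tracts do not drive admissions), scan the database, admit hits at or
#' below the family's inclusion E-value that pass reciprocal validation,
#' and repeat. Terminates when an iteration admits nothing
#' (`converged`), when `max_iterations` is reached, or when more than
#' `unrelated_fraction` of an iteration's would-be admissions fail the
#' reciprocal check — the automated analogue of "the results started to
#' retrieve unrelated hits" — in which case that iteration's admissions
#' are rolled back (`unrelated_hits`).
#'
#' @param seeds A `family_seeds`.
#' @param db Sequence tibble, already passed through
#'   [prefilter_complete()].
#' @param matrix A `subst_matrix`.
#' @param max_iterations Iteration cap.
#' @param unrelated_fraction Reciprocal-failure fraction that triggers
#'   the unrelated-hits stop.
#' @param reference_db Optional labeled seed tibble (columns of a
#'   sequence tibble plus `family`) for reciprocal validation; defaults
#'   to the harvesting family's own seeds.
#' @param mask_threshold Bias-masking threshold applied to profile
#'   queries.
#' @return List with `seeds` (enlarged `family_seeds`) and `run`, a
#'   `harvest_run` object (per-iteration admissions, flagged ids, stop
#'   reason).
#' @export
iterative_family_search <- function(seeds, db, matrix,
                                    max_iterations = 10L,
                                    unrelated_fraction = 0.5,
                                    reference_db = NULL,
                                    mask_threshold = 15L) {
  stopifnot(inherits(seeds, "family_seeds"))
  db <- as_seq_tbl(db)
  if (is.null(reference_db)) {
    reference_db <- seeds$members
    reference_db$family <- seeds$family
  }
  if (!any(seeds$members$id %in% db$id)) {
    warning("database contains none of the seed members; proceeding")
  }

  members <- seeds$members
  iterations <- list()
  stop_reason <- "max_iterations"

  for (it in seq_len(max_iterations)) {
    cur <- family_seed_set(seeds$family, members, seeds$master_id,
                           inclusion_evalue = seeds$inclusion_evalue,
                           notes = seeds$notes)
    masked <- mask_sequences(cur$members, threshold = mask_threshold,
                             matrix = matrix)
    masked$bias_segments <- NULL
    cur_masked <- family_seed_set(seeds$family, masked, seeds$master_id,
                                  inclusion_evalue = seeds$inclusion_evalue)
    pssm <- build_family_pssm(cur_masked, matrix)
    hits <- search_proteome(pssm, db,
                            evalue_cutoff = seeds$inclusion_evalue,
                            max_target_sequences = nrow(db), cbs = TRUE)
    cand <- hits[!(hits$subject_id %in% members$id), , drop = FALSE]
    if (nrow(cand) == 0L) {
      iterations[[it]] <- tibble::tibble(
        iteration = it, new_member_ids = list(character(0)),
        flagged_ids = list(character(0)))
      stop_reason <- "converged"
      break
    }
    ok <- vapply(seq_len(nrow(cand)), function(k) {
      reciprocal_check(cand[k, ], db$residues[db$id == cand$subject_id[k]],
                       reference_db, matrix)
    }, logical(1))
    flagged <- cand$subject_id[!ok]
    admitted <- cand$subject_id[ok]
    if (mean(!ok) > unrelated_fraction) {
      iterations[[it]] <- tibble::tibble(
        iteration = it, new_member_ids = list(character(0)),
        flagged_ids = list(flagged))
      stop_reason <- "unrelated_hits"
      break
    }
    iterations[[it]] <- tibble::tibble(
      iteration = it, new_member_ids = list(admitted),
      flagged_ids = list(flagged))
    if (length(admitted) == 0L) {
      stop_reason <- "converged"
      break
    }
    members <- dplyr::bind_rows(members,
                                db[db$id %in% admitted, c("id", "description",
                                                          "residues")])
  }

  run <- structure(list(
    family = seeds$family,
    iterations = if (length(iterations)) dplyr::bind_rows(iterations) else
      tibble::tibble(iteration = integer(), new_member_ids = list(),
                     flagged_ids = list()),
    stop_reason = stop_reason,
    inclusion_evalue = seeds$inclusion_evalue,
    max_iterations = max_iterations), class = "harvest_run")

  final <- family_seed_set(seeds$family, members, seeds$master_id,
                           inclusion_evalue = seeds$inclusion_evalue,
                           notes = seeds$notes)
  list(seeds = final, run = run)
}

#' @export
print.harvest_run <- function(x, ...) {
  n_new <- sum(lengths(x$iterations$new_member_ids))
  cat("<harvest_run> ", x$family, ": ", nrow(x$iterations),
      " iteration(s), ", n_new, " admission(s), stopped: ",
      x$stop_reason, "\n", sep = "")
  invisible(x)
}

#' Tidy a harvest run
#'
#' @param x A `harvest_run`.
#' @param ... Unused.
#' @return Tibble with one row per iteration: `iteration`, `n_admitted`,
#'   `n_flagged`, list-columns of the ids.
#' @export
tidy.harvest_run <- function(x, ...) {
  out <- x$iterations
  out$n_admitted <- lengths(out$new_member_ids)
  out$n_flagged <- lengths(out$flagged_ids)
  out[, c("iteration", "n_admitted", "n_flagged", "new_member_ids",
          "flagged_ids")]
}
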