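#' Specification for a synthetic protein family
#'
#' Parameters of the family simulator: a conserved ancestral core of
#' `core_length` residues drawn from background frequencies, `n_members`
#' homologs mutated independently from it at `divergence` expected
#' substitutions per site (substitutions drawn proportional to
#' `exp(lambda * s_ab)` so homologs stay detectable by score, as real
#' divergence does), indels at `indel_rate` per site (geometric length,
#' mean 2), and optional compositional-bias features: an FG-style repeat
#' tract and/or a single-residue low-complexity run inserted at a
#' homologous position (+/- 2 jitter) in every member.
#'
#' @param family Family name.
#' @param core_length Ancestral core length (>= 50 recommended).
#' @param n_members Number of mutated members to generate.
#' @param divergence Expected substitutions/site in `[0, 1)`.
#' @param indel_rate Per-site indel probability.
#' @param repeat_motif Optional short motif (e.g. `"FG"`).
#' @param repeat_copies Number of motif copies.
#' @param lcr_residue Optional residue for a low-complexity run.
#' @param lcr_length Length of the low-complexity run.
#' @param rng_seed Integer seed; all outputs are pure functions of the
#'   spec.
#' @return A `synth_family_spec` list.
#' @export
synthetic_family_spec <- function(family, core_length = 200L,
                                  n_members = 10L, divergence = 0.25,
                                  indel_rate = 0.01,
                                  repeat_motif = NULL, repeat_copies = 0L,
                                  lcr_residue = NULL, lcr_length = 0L,
                                  rng_seed = 1L) {
  if (divergence >= 1 || divergence < 0) stop("divergence must be in [0, 1)")
  stopifnot(core_length >= 1, n_members >= 1, indel_rate >= 0,
            repeat_copies >= 0, lcr_length >= 0)
  structure(list(family = family, core_length = as.integer(core_length),
                 n_members = as.integer(n_members),
                 divergence = divergence, indel_rate = indel_rate,
                 repeat_motif = repeat_motif,
                 repeat_copies = as.integer(repeat_copies),
                 lcr_residue = lcr_residue,
                 lcr_length = as.integer(lcr_length),
                 rng_seed = as.integer(rng_seed)),
            class = "synth_family_spec")
}

# conditional substitution probabilities Pr(b | a) ~ p_b exp(lambda s_ab),
# identity excluded (a substitution is a change)
substitution_kernel <- function(matrix) {
  p <- matrix$background_freqs
  s20 <- matrix$scores[AA20, AA20]
  k <- sweep(exp(matrix$ungapped_lambda * s20), 2, p, "*")
  diag(k) <- 0
  sweep(k, 1, rowSums(k), "/")
}

mutate_member <- function(core_chars, divergence, indel_rate, kernel, p) {
  out <- character(0)
  i <- 1L
  n <- length(core_chars)
  while (i <= n) {
    if (indel_rate > 0 && stats::runif(1) < indel_rate) {
      len <- stats::rgeom(1, 0.5) + 1L
      if (stats::runif(1) < 0.5) {  # deletion of len sites
        i <- i + len
        next
      } else {                      # insertion of len background residues
        out <- c(out, sample(AA20, len, replace = TRUE, prob = p))
      }
    }
    a <- core_chars[i]
    if (stats::runif(1) < divergence) {
      out <- c(out, sample(AA20, 1L, prob = kernel[a, ]))
    } else {
      out <- c(out, a)
    }
    i <- i + 1L
  }
  if (length(out) == 0L) out <- core_chars[1]
  out
}

#' Sample a synthetic protein family
#'
#' Generates the ancestral core (first row, id `<family>_core`) and
#' `n_members` divergent homologs. Fully reproducible from the spec's
#' `rng_seed`.
#'
#' @param spec A `synth_family_spec`.
#' @param matrix A `subst_matrix` driving the substitution kernel;
#'   defaults to bundled BLOSUM62.
#' @return Sequence tibble: core followed by members
#'   (`<family>_m01`, ...).
#' @export
sample_family <- function(spec, matrix = NULL) {
  stopifnot(inherits(spec, "synth_family_spec"))
  if (is.null(matrix)) matrix <- load_substitution_matrix("BLOSUM62")
  set.seed(spec$rng_seed)
  p <- matrix$background_freqs
  kernel <- substitution_kernel(matrix)
  core <- sample(AA20, spec$core_length, replace = TRUE, prob = p)

  tract <- ""
  if (!is.null(spec$repeat_motif) && spec$repeat_copies > 0L) {
    tract <- strrep(spec$repeat_motif, spec$repeat_copies)
  }
  lcr <- ""
  if (!is.null(spec$lcr_residue) && spec$lcr_length > 0L) {
    lcr <- strrep(spec$lcr_residue, spec$lcr_length)
  }
  tract_pos <- max(1L, spec$core_length %/% 2L)
  lcr_pos <- max(1L, (3L * spec$core_length) %/% 4L)

  decorate <- function(chars) {
    s <- paste(chars, collapse = "")
    L <- nchar(s)
    if (nzchar(tract)) {
      pos <- min(max(1L, tract_pos + sample(-2:2, 1L)), L)
      s <- paste0(substr(s, 1L, pos), tract, substr(s, pos + 1L, L))
    }
    if (nzchar(lcr)) {
      L <- nchar(s)
      pos <- min(max(1L, lcr_pos + sample(-2:2, 1L)), L)
      s <- paste0(substr(s, 1L, pos), lcr, substr(s, pos + 1L, L))
    }
    s
  }

  rows <- vector("list", spec$n_members + 1L)
  rows[[1]] <- tibble::tibble(id = paste0(spec$family, "_core"),
                              description = "ancestral core",
                              residues = decorate(core))
  for (k in seq_len(spec$n_members)) {
    mem <- mutate_member(core, spec$divergence, spec$indel_rate, kernel, p)
    rows[[k + 1L]] <- tibble::tibble(
      id = sprintf("%s_m%02d", spec$family, k),
      description = sprintf("synthetic homolog divergence %.2f",
                            spec$divergence),
      residues = decorate(mem))
  }
  dplyr::bind_rows(rows)
}

#' Insert a repeat tract into a sequence
#'
#' @param seq Residue string or single-row sequence tibble.
#' @param motif Short motif to repeat (e.g. `"FG"`).
#' @param copies Number of copies (`>= 1`).
#' @param position Insertion point: the tract goes after this 1-based
#'   position (0 = prefix).
#' @return The modified residue string (or tibble, matching the input).
#' @export
inject_repeats <- function(seq, motif, copies, position) {
  stopifnot(copies >= 1, nzchar(motif))
  tib <- is.data.frame(seq)
  s <- if (tib) seq$residues[[1]] else seq
  stopifnot(position >= 0, position <= nchar(s))
  tract <- strrep(motif, copies)
  out <- paste0(substr(s, 1L, position), tract,
                substr(s, position + 1L, nchar(s)))
  if (tib) {
    seq$residues[[1]] <- out
    seq
  } else {
    out
  }
}

random_decoys <- function(n, p, len_range = c(120L, 400L), prefix = "d") {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  tibble::tibble(
    id = sprintf("%s%03d", prefix, seq_len(n)),
    description = "random decoy",
    residues = vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE, prob = p), collapse = "")
    }, character(1)))
}

#' Generate a synthetic detection benchmark
#'
#' Builds the full evaluation surface: for each family a training split
#' kept as seeds and one held-out member per expected-true
#' (species, family) cell embedded in that species' decoy proteome;
#' expected-absent cells (sampled to an exact count) contain no family
#' member. Defaults mirror the evaluated study design scaled to desk
#' size: 15 species, 10 families, divergence 0.25, 200 decoys per
#' proteome, and an absent fraction of 134/540.
#'
#' @param n_species,n_families Grid dimensions.
#' @param absent_fraction Fraction of cells expected absent; the absent
#'   cell count is `round(absent_fraction * n_species * n_families)`.
#' @param decoys_per_proteome Random background sequences per proteome.
#' @param core_length,divergence,indel_rate Family simulator parameters.
#' @param n_training Training members (seeds) per family.
#' @param repeat_families How many families (taken from the first) carry
#'   an FG-repeat tract (12 copies), for masking-sensitivity fixtures.
#' @param rng_seed Integer seed.
#' @param matrix A `subst_matrix`; defaults to bundled BLOSUM62.
#' @return A `synthetic_benchmark` list: `proteomes` (named list of
#'   sequence tibbles), `families` (named list of `family_seeds`),
#'   `expected` (an `expected_composition`), `manifest`.
#' @export
make_benchmark <- function(n_species = 15L, n_families = 10L,
                           absent_fraction = 134 / 540,
                           decoys_per_proteome = 200L,
                           core_length = 200L, divergence = 0.25,
                           indel_rate = 0.01, n_training = 8L,
                           repeat_families = 0L, rng_seed = 1L,
                           matrix = NULL) {
  stopifnot(absent_fraction >= 0, absent_fraction < 1)
  if (decoys_per_proteome == 0L && n_families == 0L) {
    stop("empty proteomes: no decoys and no families")
  }
  if (is.null(matrix)) matrix <- load_substitution_matrix("BLOSUM62")
  set.seed(rng_seed)

  species <- sprintf("sp%02d", seq_len(n_species))
  fams <- sprintf("fam%02d", seq_len(n_families))
  grid <- expand.grid(species = species, family = fams,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$species, grid$family), ]
  n_absent <- round(absent_fraction * nrow(grid))
  absent_idx <- sample(nrow(grid), n_absent)
  grid$expected <- TRUE
  grid$expected[absent_idx] <- FALSE

  fam_seeds <- stats::setNames(
    sample.int(.Machine$integer.max - 1L, n_families), fams)

  families <- list()
  truth <- list()   # per family: tibble species/id/residues
  for (fi in seq_along(fams)) {
    fam <- fams[fi]
    sp_true <- grid$species[grid$family == fam & grid$expected]
    spec <- synthetic_family_spec(
      fam, core_length = core_length,
      n_members = n_training + length(sp_true),
      divergence = divergence, indel_rate = indel_rate,
      repeat_motif = if (fi <= repeat_families) "FG" else NULL,
      repeat_copies = if (fi <= repeat_families) 12L else 0L,
      rng_seed = fam_seeds[[fam]])
    mem <- sample_family(spec, matrix)
    train <- mem[seq(2L, 1L + n_training), ]
    held <- mem[seq(2L + n_training, nrow(mem)), ]
    families[[fam]] <- family_seed_set(fam, train)
    if (length(sp_true) > 0L) {
      truth[[fam]] <- tibble::tibble(
        species = sp_true,
        id = sprintf("%s_%s_true", sp_true, fam),
        residues = held$residues)
    }
  }
  truth_all <- dplyr::bind_rows(truth)

  proteomes <- list()
  for (sp in species) {
    dec <- random_decoys(decoys_per_proteome, matrix$background_freqs,
                         prefix = paste0(sp, "_d"))
    planted <- truth_all[truth_all$species == sp, ]
    prot <- dplyr::bind_rows(
      dec,
      tibble::tibble(id = planted$id,
                     description = "held-out family member",
                     residues = planted$residues))
    proteomes[[sp]] <- as_seq_tbl(prot)
  }

  grid$truth_ids <- ifelse(
    grid$expected, sprintf("%s_%s_true", grid$species, grid$family), "")
  ec <- expected_composition(tibble::as_tibble(grid))

  manifest <- list(
    n_species = n_species, n_families = n_families,
    n_absent = n_absent, decoys_per_proteome = decoys_per_proteome,
    core_length = core_length, divergence = divergence,
    indel_rate = indel_rate, n_training = n_training,
    repeat_families = repeat_families, rng_seed = rng_seed,
    rng_kind = "Mersenne-Twister", family_seeds = as.list(fam_seeds))

  structure(list(proteomes = proteomes, families = families,
                 expected = ec, manifest = manifest),
            class = "synthetic_benchmark")
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  g <- glance(x$expected)
  cat("<synthetic_benchmark> ", g$n_species, " species x ", g$n_families,
      " families, ", g$n_expected, " expected-true cell(s), ",
      g$n_absent, " absent, seed ", x$manifest$rng_seed, "\n", sep = "")
  invisible(x)
}
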