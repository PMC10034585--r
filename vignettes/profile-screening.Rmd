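---
title: "Family-specific PSSM screening: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-specific PSSM screening: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profscan)
```

profscan builds family-specific position-specific scoring matrices
(PSSMs) from curated sets of divergent protein homologs, hard-masks
compositionally biased sequence, scans proteomes with exhaustive
position-specific Smith–Waterman search under Karlin–Altschul E-value
statistics, and scores detection sensitivity against an
expected-composition gold standard. The motivating use case is the
nucleoporin (NUP) superfamily — large, fast-evolving nuclear pore
complex subunits riddled with FG repeats, TPR/WD40-like repeats and
other low-complexity tracts that defeat generic profile searches — but
every stage is family-agnostic.

This vignette documents the models, the tunable parameters, the
numerical choices, and the places where the design was genuinely open.

## Profile construction

A family is represented by a `family_seeds` object: members, a
designated representative (the *master*), and a family-specific
inclusion E-value used during harvesting. Profiles live in master
coordinates:

1. **Master–slave alignment.** Each member is aligned to the master by
   Smith–Waterman with affine gaps (`gap_open = 11`, `gap_extend = 1`,
   a length-*g* gap costing `11 + g`). Only the single best HSP per
   member is used, and members whose HSP spans less than half the
   master are excluded — fragments should not dilute columns. Member
   insertions relative to the master are dropped from the profile and
   only counted in a log; this is the classic checkpoint-PSSM
   coordinate model, and it is what makes column bookkeeping exact.
2. **Position-based weighting.** Henikoff weights: in a column with
   `r` distinct residue types, a residue shared by `s` members
   contributes `1/(r*s)`; member weights are column means, normalised
   to sum to one. Redundant near-duplicates therefore cannot dominate
   a profile, and the construction is invariant under duplication and
   reordering of the member set (both are tested properties).
3. **Pseudocount mixing.** Observed weighted frequencies `f` are mixed
   with matrix-derived target frequencies
   `g_a = sum_b f_b Pr(a|b)`, `Pr(a|b) ∝ p_a exp(λ s_ab)`, as
   `Q = (α f + β g)/(α + β)` with `β = 10` and `α = N_c − 1`, where
   `N_c` is the mean number of distinct residue types per column. A
   single-sequence alignment has `α = 0` and falls back entirely on
   the substitution matrix, which is exactly the behaviour wanted for
   a family anchored on one representative. `Pr(a|b)` is normalised
   over `a`; the unnormalised kernel sums only approximately to one,
   and normalising keeps the `Q` row-sum invariant exact.
4. **Integer log-odds.** `s_a = round(log(Q_a / p_a) / scale)` with
   `scale = ln 2 / 2` (half-bit units, the ASCII-PSSM convention),
   rounding half away from zero. The 21st column (`X`) is fixed at −1
   so masked residues can never contribute positive signal. Columns
   with no aligned residue fall back to the substitution-matrix row of
   the master residue and are flagged.

Rounding to integers perturbs the per-row normalisation
`sum_a p_a exp(scale · s_a)`; the accepted band is `[0.8, 1.25]`,
checked as a test invariant.

The bundled matrix is BLOSUM62 with Robinson–Robinson background
frequencies. The published frequency table sums to 0.99988, so it is
renormalised on load; the ungapped `λ` is solved from the
Karlin–Altschul identity at load time (it comes out at the standard
0.3176) rather than hard-coded, so the normalisation invariant holds to
numerical precision. Ungapped `K = 0.134` and gapped `K = 0.041` are
the standard published constants; no per-profile simulation calibration
is run (a deliberate determinism/runtime trade-off — the hook is the
`gapped_K`/`scale` arguments of `pssm_from_msa()`).

## Compositional-bias masking

Biased tracts are found by optimal ungapped local alignment of the
sequence against an infinite homopolymer of each residue type: the
maximal-sum segment of per-position scores `s(residue, seq_i)`
(leftmost on ties). If the best of the 20 scores exceeds the threshold,
occurrences of that residue type inside the segment are replaced by
`X`, and the scan repeats on the masked sequence (alphabetical
tie-break between residue types at equal score) until nothing exceeds
the threshold.

The working threshold is **15**, deliberately more aggressive than the
classic default of 40: the target families contain FG repeats and
other diffuse biases that a conservative threshold misses. At 15,
random background sequence also picks up occasional short segments;
that is expected and harmless, because masked residues score a flat −1
in search. Masking is hard (to `X`) rather than soft because search
statistics are computed from the masked sequence. Idempotence and
monotonicity in the threshold are tested invariants.

## Search statistics

Scanning is exhaustive dynamic programming — no two-hit seeding, no
x-drop: at desk scale (hundreds of subjects per proteome) a full
Gotoh pass per subject costs milliseconds in compiled code, and
exactness is what lets the implementation be checked against a
brute-force enumeration oracle (all monotone matchings, instances up
to profile length 6 × subject length 8; ≥ 500 random cases in the
suite).

Raw scores are converted with the Karlin–Altschul transform
`S' = (λS − ln K)/ln 2`, `E = m'n' 2^(−S')`, with the standard
edge correction `ℓ = ⌊ln(K m n)/H⌋` (`H` = profile relative entropy
per position, floored at 0.01 nats), `m' = max(1, m − ℓ)`,
`n' = max(#seqs, n − #seqs·ℓ)`.

**Composition-based statistics** (on by default, matching the
protocol's `composition-based statistics = 1`) re-solve `λ` per
subject from
`sum_a q_a (1/L) sum_i exp(λ s_ia) = 1`, where `q` is the subject
composition with a pseudocount of one per residue type. Subjects
enriched in residues the profile rewards get a smaller `λ` and hence
deflated bit scores — this is what keeps FG-repeat-bearing bystanders
from accumulating inflated significance. This is an explicit,
documented dialect of compositional adjustment, not a bit-exact clone
of any particular BLAST mode. Three numerical details:

* `λ = 0` is always a trivial root; the solver brackets the
  non-trivial positive root and falls back to the global `λ` with a
  warning if none exists below `10λ`.
* Subjects shorter than 30 residues skip the rescale (composition too
  noisy to calibrate on).
* For a subject whose composition equals the background, the
  rescaled root sits at the profile's own background root, which
  integer rounding of the log-odds shifts a few percent away from
  `ln 2 / 2`; the test suite therefore checks the root against an
  independent bisection oracle at 1e-6 and the background fixed point
  at a rounding-aware tolerance.
* Subjects whose E-value under the global `λ` misses the cutoff by
  more than a factor of 1e6 (≈ 20 bits) are not re-solved; a
  composition shift large enough to bridge that gap does not occur for
  score ranges the profiles produce.

Hit lists follow the screening protocol shape: best HSP per subject
(`max_hsps = 1`), `E ≤ 10`, at most 20 subjects, sorted by E-value
with deterministic ties (higher bit score, then lexicographic subject
id) so rank matrices are reproducible across platforms. DP tracebacks
prefer diagonal over up over left, and the best cell is the leftmost
maximum.

## Iterative harvesting

`iterative_family_search()` automates the delineation loop: build a
profile from the current members, scan the database, admit hits at or
below the family's inclusion E-value that pass **reciprocal
validation** (the HSP region aligned back against labelled reference
seeds must hit the harvesting family best), rebuild, repeat. The
database is first reduced to complete sequences
(`prefilter_complete()`: description-keyword blacklist
"fragment"/"partial" plus a length floor of half the master).

Two termination rules beyond the iteration cap:

* **converged** — an iteration admits nothing;
* **unrelated_hits** — more than half of an iteration's would-be
  admissions fail the reciprocal check. The original stop rule is a
  manual judgement ("the results started to retrieve unrelated
  hits"); a majority of reciprocal failures is the automated proxy
  chosen here, and the iteration's admissions are rolled back.

Per the curation protocol, iteration profiles are built from
*masked* copies of the current members (threshold 15) so biased tracts
cannot drive admissions, while the returned member set — from which
export profiles are built — stays unmasked. Default inclusion
thresholds: 1e-5, with 1e-10 suggested for repeat-rich families.

## Benchmarking

The gold standard is an `expected_composition`: a full species ×
family grid where each expected-true cell names its true protein
id(s). The canonical design is 15 species × 36 families with 134
literature-absent cells, i.e. 406 evaluated entries — an arithmetic
the constructor validates and the test suite pins.

Detection is scored by the **top-hit criterion**: a cell counts as
detected only when the true protein ranks first in that profile's hit
list; lower ranks appear in the rank matrix but score as false
negatives — this matches how the published coverage tables are
counted. For expected-absent cells, any call at `E ≤ 1e-5` counts as a
false positive (the source protocol reports zero false positives but
does not print its criterion; 1e-5 is this package's explicit choice).
TPR and FNR are percentages rounded half-up to one decimal, and method
deltas are differences of the rounded rates — again matching the
printed arithmetic, which the acceptance suite reproduces exactly
(92.4/7.6 from 375/31, 79.6/20.4 from 246/63, and so on).

HMMER `tblout` files are ingested for cross-method comparison
(`read_hmmer_tblout()`); profile-HMM search itself is out of scope.

## The synthetic benchmark

Real proteome-level reproduction needs external downloads (UniProt
proteomes, deposited profile libraries), so the package ships a
generator that gives every stage a self-contained test surface:

* ancestral cores drawn from background frequencies;
* members mutated at a per-site substitution rate (the *divergence*),
  with substitutions sampled from the BLOSUM62-conditional
  `Pr(b|a) ∝ p_b exp(λ s_ab)`, excluding the identity — homologs stay
  detectable by score, as real divergence behaves;
* indels at a per-site rate (geometric length, mean 2);
* optional FG-repeat or single-residue low-complexity tracts inserted
  at a homologous position (± 2 jitter) in every member, so profiles
  learn them unless masked — this is precisely what makes the
  masking-sensitivity comparison meaningful;
* per-family training/held-out splits, decoy proteomes, and an exact
  count of absent cells.

Default study conditions: 15 species × 10 families, divergence 0.25,
core length 200, 8 training members, 200 decoys per proteome, absent
fraction 134/540. At divergence 0.2 with a 1000-residue core,
positional identity of members to the core sits in the 0.75–0.88 band
(a frozen empirical regression bound). All outputs are pure functions
of the spec seed; R's Mersenne–Twister is used with the integer seed
recorded in the manifest (base R has no counter-based generator, and
reproducibility is what matters here).

What the generator does **not** emulate: phylogenetic structure
(tree-shaped divergence, rate heterogeneity across sites), domain
architecture (real nucleoporins share domains across families),
database redundancy, and annotation noise. Passing the synthetic
recovery property (held-out TPR ≥ 90 %, zero false positives at
`E ≤ 1e-5`) therefore demonstrates that the machinery — profile
construction, statistics, ranking — is sound, not that real-proteome
sensitivity will match; the published real-data rates are reproduced
at the arithmetic level, not re-measured.

Problem sizes used by the test and acceptance runs (chosen as
desk-scale conditions: each full detection run is a few tens of
seconds on one core): the default benchmark above over 5 seeds for
recovery, a 6 species × 4 family all-FG fixture for the
masked-vs-unmasked comparison, and a 20-member family (10 seeded, 10
hidden) among 200 decoys for harvest convergence.

## Known limitations

* E-values are a calibrated dialect: gapped `λ` reuses the half-bit
  scale and `K = 0.041` rather than per-profile simulation, and the
  composition rescale is not a bit-exact BLAST CBS clone. Ranks — the
  quantity the evaluation depends on — are unaffected by monotone
  miscalibration within a subject; absolute E-values should be read
  with that in mind.
* Master-coordinate profiles discard member insertions; families whose
  conserved core lies in a region the master lacks need a different
  master, not a different algorithm.
* The PSSM ASCII format prints frequencies at 4 decimals; everything
  else round-trips bit-exactly, frequencies to 5e-5.
* Numeric identity with any externally deposited profile library is
  not claimed — behavioural equivalence is.
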