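---
title: "Methods: in silico primer coverage evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico primer coverage evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primercov)
```

## The procedure

`primercov` evaluates oligonucleotide primers against a sequence database in
four stages:

1. **Quality control.** Every target sequence is scanned for characters
   outside `{A, C, G, T}` — uracil from RNA-derived entries, IUPAC ambiguity
   codes from consensus building, gaps, or stray symbols. Flags are reported;
   what to do with them is the user's call. The default policy (`keep`)
   retains flagged sequences, `drop` removes them. There is deliberately no
   "mask" policy (replace with N): masking would silently change match
   arithmetic, whereas keep/drop leave the data either untouched or absent.
2. **Grouping.** Sequences are grouped per sequence (default), per taxon at
   a chosen taxonomic level, or per clade. Clades are operationalised as
   lineage-string prefixes: every distinct non-empty prefix of any depth is
   a group whose members are all sequences extending it. No tree is
   inferred; with lineages of bounded depth the prefix lattice *is* the
   clade structure, and nested groups are evaluated independently.
3. **Search.** Each primer is slid along each analysed sequence. A window
   matches when the number of positions whose target character is not in
   the primer's IUPAC class is at most the mismatch budget. For pairs,
   every forward hit `f` and reverse hit `r` with `f.end <= r.start` forms
   a candidate amplicon; optional bounds on the amplicon length filter the
   candidates.
4. **Coverage.** A group is covered when any member sequence is matched
   (for pairs: amplified). Coverage is `100 * covered / total` groups.
   Positional summaries average one representative hit per covered
   sequence.

## Matching semantics and their assumptions

* **Substitutions only.** The mismatch model has no indels: the window
  length always equals the primer length, so positions are well defined and
  the search is an exact sliding-window Hamming computation. This mirrors
  how PCR mismatch tolerance is usually screened in silico; primers that
  would anneal with a bulge are out of scope.
* **Degenerate bases expand in the primer, not the target.** A primer `R`
  accepts target `A` or `G`. A degenerate character in the *target* never
  matches by set intersection — target `N` against primer class `{A, G}`
  costs one mismatch, and even primer `N` does not accept target `N`
  (classes contain only the four bases). Rationale: the semantics stay
  deterministic and oracle-checkable, and QC has already surfaced such
  characters so the user can decide to drop them. The alternative
  (intersection matching) would count an all-N stretch as a perfect primer
  site.
* **Strand handling.** Primers are searched exactly as written; the file
  format's contract is that primers are already oriented for amplification.
  Because some published collections store reverse primers on the sense
  strand, `rc_reverse = TRUE` reverse-complements reverse primers
  (IUPAC-aware) before searching, covering both conventions explicitly
  rather than guessing. Primers of unknown role are searched in both
  orientations and a hit in either counts.
* **Amplicon span includes both primer footprints.** `length = rev.end -
  fwd.start`, the physical PCR product. Published descriptions of "the
  fragment between the primers" are ambiguous between product and insert;
  we chose the product because length bounds are usually platform read
  length constraints, which see the product. The insert length is always
  `length - nchar(fwd) - nchar(rev)` if needed.
* **Representative hits.** When a sequence has several hits (or several
  valid amplicons), coverage uses existence, while positional summaries use
  one representative: the leftmost start, ties broken by shortest
  (amplicons) or smallest end (single primers). This mimics the dominant
  short product in real amplification and keeps multi-hit sequences from
  dominating the means. All ordering is by ascending `(start, end)`; the
  engine contains no randomness.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `max_mismatches` | 0 | substitutions tolerated per primer footprint; 0 = exact IUPAC match |
| `min_len`, `max_len` | unbounded | bounds (nt) on the primer-inclusive amplicon span |
| `rc_reverse` | `FALSE` | reverse-complement reverse primers before searching |
| `qc_policy` | `keep` | retain or drop sequences with non-ACGT characters |
| `threshold_pct` | 75 | species-level coverage required for a primer to enter pair construction |
| `domain_min_cov` | 0 (exclusive) | coverage above this counts as "covers the domain" |

Thresholds are compared on unrounded values; tables print percentages and
positions with two decimals. Written files use 1-based inclusive
coordinates (the field convention); all internal arithmetic is 0-based
half-open.

## Case-study orchestration

`run_case_study()` reproduces the analysis shape of a primer survey:
species-level single-primer evaluation on a bacterial and an archaeal
database; classification of each primer by the domain(s) it actually covers
(coverage strictly above `domain_min_cov` on that domain's database; both →
universal, neither → none); per-domain construction of all forward ×
reverse combinations among primers at or above `threshold_pct`; and
re-evaluation of those pairs on the same domain's database, ranked by
coverage descending, then mean amplicon length ascending, then name.

Three open points were resolved as package conventions: eligibility is
computed per domain (a primer enters bacterial pairs by its coverage on the
bacterial database only); unknown-role primers are eligible on both sides
of a pair, including paired with themselves, since "all combinations" gives
no reason to exclude them; and the pair stage reuses the single-primer
mismatch budget, as no stage-specific setting is described anywhere.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` builds databases with a known taxonomy tree, uniform
(or GC-biased) random backgrounds, and primer/pair sites *planted* at known
offsets, optionally with an exact number of substitutions injected outside
the primer's IUPAC classes. Backgrounds are screened at the fixture's
screening budget: any accidental occurrence of a planted primer (including
the reverse complement of unknown-role primers and both members of a pair)
anywhere except its planted offsets triggers regeneration of that sequence.
Ground truth — which sequences a primer recovers at each budget, at which
offsets, and hence coverage and positional means per grouping mode — is
therefore derived purely from the construction record, not from running the
search.

This emulates what matters for correctness testing: exact planted truth,
degenerate codes, mismatch gating, taxonomic structure, multiple grouping
modes. It does **not** emulate real marker genes: there is no conserved /
variable region structure, no phylogenetic correlation between sequences of
related taxa, no length variation, and no chimeras. A green fixture test
therefore establishes that the arithmetic is exact on known ground truth;
it says nothing about which real-world primers are good, and nothing about
behaviour under indel-type variation, which the model excludes.

Default fixture scales (a few taxa, 2–5 sequences per taxon, 150–320 nt
backgrounds, 18–20 nt primers) are chosen so that a planted-primer
collision in random background is essentially impossible (length ≥ 12 nt
makes a chance 0-mismatch hit ~4^-12 per window) while keeping the screened
regeneration loop fast; the screening makes truth exact regardless.

The canned `mini_oral_fixture()` (3 phyla / 8 species / 40 bacterial
sequences, 1 phylum / 3 species / 9 archaeal sequences, 5 single primers,
2 pairs, fixed seeds) exists for documentation, smoke tests and the
byte-identical rerun check.

## Numerical and formatting choices

* Group keys are full lineage prefixes (`"Bacteria;Firmicutes"`), never
  bare taxon names, so homonymous taxa at different ranks cannot merge.
* Sequences lacking a lineage are excluded from taxonomy-requiring modes
  and counted in the log, rather than pooled into a pseudo-taxon that would
  distort coverage.
* Taxonomy files have no header line; a first line that does not parse is
  an error, not a header. Lineages must be rectangular (same depth per
  run); a single trailing semicolon is tolerated.
* Empty results are values, not errors: a primer with no hits has 0%
  coverage and absent means; zero groups is an error (nothing to assess).
* Reruns are byte-identical: no timestamps are written, group keys are
  sorted, and `run_config.json` omits the output directory (it is implied
  by location).

## Limitations

* No thermodynamics: melting temperature, ΔG, 3′-end stability and primer
  dimers are not modelled; coverage is purely sequence-combinatorial.
* Substitution-only matching (see above).
* Clades come from lineage strings, not from an inferred phylogeny.
* The download module's live NCBI transport is exercised only manually;
  offline correctness is guaranteed for batching, ordering, retry and
  failure reporting via the injected stub transport.
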