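---
title: "Modeling and calling Sμ–Sα class-switch junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and calling Sμ–Sα class-switch junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakjoin)
```

## Scope and model

`breakjoin` analyzes single-end HTGTS-style reads of the form *bait prefix +
prey segment*: linear-amplification PCR from a fixed 5′ Sμ primer runs
through the bait-side break and continues into whatever sequence was joined
there. The package does three things: it models the locus geometry, it
simulates such libraries with known per-read truth, and it calls and
summarizes junctions the way switch-region junction studies report them.

### Locus geometry

All coordinates are 1-based inclusive in a locus-local frame whose forward
direction is Sμ→Sα→Cα (telomere→centromere); on the reference assembly the
mouse IgH locus lies on the minus strand, which the window's `strand_sense`
records as metadata. The default analysis window is
chr12:114,491,001–114,511,000 — 20 kb centered on core Sα — tiled by 100
bins of 200 bp. The window width, bin width and bait primer are the printed
values for this assay; the *core/distal split is not printed anywhere we
know of*, so the package defaults to core = the central 4 kb and distal =
everything downstream of core through the window end, both configurable in
the locus config. The bait break sits at position 60 of a 400-bp bait
reference: far enough from the 20-bp primer that anchoring and germline
detection are distinct events, and leaving ~90 bp of prey sequence in a
150-bp read, comfortably above the mapping floor.

Because the package operates desk-scale against a single window rather than
a genome build, the bundled references are *synthetic*: uniform-random DNA
generated deterministically in code. Real S regions are long tandem G-rich
repeats; uniform-random sequence has no repeat structure, so mapping
ambiguity in these simulations is far rarer than it would be against a real
switch region. Conclusions about ambiguity rates therefore do not transfer
to real data; everything about the junction-boundary arithmetic does.
User-supplied FASTA references are accepted wherever the synthetic ones are
used.

### The simulator

Each non-germline template is generated as:

1. **Acceptor break**: truncated normal around the core-Sα midpoint,
   sd `break_spread` (default 700 bp, keeping ~99% of breaks inside the
   4-kb core — breaks are strongly core-enriched), clamped into the window.
2. **Resection**: geometric with mean `resection_mean`, shifting the join
   position downstream toward Cα. Geometric is a deliberate one-parameter,
   memoryless choice; any replacement must preserve the property that a
   larger mean strictly increases the fraction of joins reaching the distal
   zone. Resection is modeled on the acceptor side only, because the
   readout it feeds — junctions appearing in distal Cα — only depends on
   how far the acceptor-side join moved.
3. **Junction chemistry**: with probability `insertion_prob` an untemplated
   insert of 1–`ins_max` random bases (and no MH); otherwise a target MH
   drawn from the preset's `mh_prior` and *planted* by scanning ±50 bp
   (`search_window`) around the resected position for the bait end's
   terminal k-mer, decrementing the target until an occurrence is found.
   The realized junction may carry more MH than planted when flanking bases
   coincidentally match; the truth table therefore records `realized_mh`,
   recomputed post hoc as the maximal exact overlap, and caller accuracy is
   always judged against that sequence-true value.
4. **Orientation**: inverted capture with probability `inversion_prob`.
5. **Library structure**: a deterministic `round(germline_fraction ×
   n_reads)` of templates are germline (bait reference continuing past the
   break — the residue AflII blocking leaves), junction templates receive
   Poisson(`duplicate_rate`) PCR copies, and every emitted copy gets
   independent uniform substitution errors (`error_rate`).

The presets encode the qualitative c-NHEJ vs A-EJ contrast, not measured
distributions (the source assay reports figure-level readouts, not
parametric fits): `cnhej` = resection mean 150 bp, MH prior peaked at 0–1,
10% inversions; `aej` = resection mean 1,200 bp, MH prior peaked at 1–5 bp
(the classic MMEJ range), 25% inversions. `break_spread`, insertion rates
and all library parameters are exposed. Simulated library sizes used in the
package's own checks are 1,000–10,000 reads, which give sub-percent
standard errors on the summary fractions while keeping a full run in tens
of seconds.

### The caller

Anchoring takes the longest read prefix matching the bait reference with at
most `tolerance` mismatches (default 0): shorter than the primer →
`unanchored`; at least `G = 10` bases past the break → `germline`. G = 10
makes a chance continuation (probability 4⁻¹⁰) negligible while still
catching germline fragments quickly.

Prey mapping finds the longest read suffix occurring in the prey reference
on either strand with at most `tolerance` mismatches and length ≥
`min_len = 15` (a 15-mer has ~4 × 10⁻⁵ chance of a spurious hit in 2 × 20
kb). The implementation bisects over the suffix start `j`: if `read[j..]`
occurs somewhere, so does `read[j+1..]`, so "has a hit" is monotone in `j`
and the minimal `j` — i.e. the longest suffix — is found in O(log L)
scans. This is provably equivalent to the exhaustive all-suffix,
all-position, both-strand scan, and the test suite verifies it against a
literal brute-force enumeration. Two candidates tying on (length,
mismatches) at different loci are reported `ambiguous`, never silently
resolved. When `tolerance > 0`, the five junction-proximal bases of the
prey match must still be exact — MH calling is meaningless if the overlap
bases are not.

At the boundary, with bait end `i*` and prey start `j*`:
`mh_len = max(0, i* − j* + 1)`, `insertion_len = max(0, j* − i* − 1)`;
the two are mutually exclusive by construction. A junction with MH can be
drawn anywhere inside the homology; the package canonicalizes by maximal
bait extension (bait claims the MH; the reported prey coordinate is
advanced past it, downstream in reading direction on either strand), which
makes `bait_end_i`, `prey_pos` and `mh_len` mutually consistent and
matches the oracle's canonical form.

Deduplication marks records sharing the exact key `(prey_pos, strand,
bait_end_i)` beyond the first (ordered by read id). The offset-based
criterion of the original HTGTS pipeline lives in its own software; the
exact-key rule is our stated approximation.

## Numerical and degenerate-input conventions

- `deletion_inversion_ratio` returns an `undefined` flag (not an error) at
  zero inversions; `long_resection_fraction` and `mh_spectrum` flag empty
  denominators as `NA`/`empty`.
- `compare_groups_ttest` is the pooled-variance Student's t (the assay's
  stated test; Welch behind a flag, no multiple-testing correction because
  none is applied upstream). Two zero-variance groups give `t = 0, p = 1`
  at equal means and a flagged infinite t otherwise.
- The MH spectrum caps at 10 (overflow pooled) and reports
  insertion-bearing junctions as their own `ins` class by default, so the
  blunt (MH = 0) fraction is not diluted; they can be folded into MH 0.
- The long-resection denominator is all in-window junctions (deletional +
  inversional). The source figures do not print their denominator; this
  choice is self-consistent with the window-restricted landscape and is
  documented, not asserted as theirs.
- Annealing ties (two equidistant k-mer occurrences) break downstream;
  break positions and resection joins are clamped into the window with a
  `read_length + search_window` margin so every simulated read has a full
  prey segment.
- Libraries are pooled by raw-count concatenation with per-library
  provenance and no cross-library dedup; per-library proportions are
  reported rather than depth-normalized pooled percentages, since the
  upstream normalization is unspecified.

## Known limitations

- **Dedup site saturation.** Planting MH relocates joins onto the few
  genomic sites carrying the bait's terminal k-mer (a 5-bp MH has ~20
  eligible sites in 20 kb), so at realistic depths many genuinely distinct
  junctions share an exact key and are collapsed — preferentially the
  high-MH classes. This saturation is a real property of "unique junction"
  counting in this assay class, not just of the simulator. Consequently the
  MH-spectrum truth-recovery check simulates `duplicate_rate = 0` and calls
  with `dedup = FALSE` (the correct configuration for a library known to
  carry no PCR duplicates); preset-contrast readouts use the full default
  pipeline, where the contrast direction is robust to saturation.
- **Error-induced insertions.** A substitution error adjacent to the
  junction displaces the prey match start and surfaces as a short apparent
  insertion; with default error rates this inflates the `ins` class among
  *unique* junctions (error-bearing reads rarely share keys, so dedup
  enriches them). Truth-recovery guarantees are stated for error-free
  libraries only.
- Single acceptor window per run; no genome-wide prey space, chimeric
  multi-junction reads, indel sequencing errors, paired ends, or
  quality-aware calling.
- Preset parameters are modeling choices; none of the simulator's
  distributions is calibrated to a measured library, so passing checks
  demonstrate internal correctness of the calling arithmetic and the
  qualitative pathway contrast, not quantitative agreement with any real
  genotype.

## What the package's own checks compute

The test suite and `scripts/acceptance.R` recompute, at run time: the
20-kb/100-bin window arithmetic; 100% agreement of junction calls with a
brute-force split-enumeration oracle on 1,000 error-free reads; total
variation ≤ 0.02 between called and realized MH spectra on an error-free
n = 10,000 A-EJ library; read-count conservation across statuses on every
library including all-germline, all-unmapped and empty fixtures; strictly
increasing long-resection percentages across resection means
150/600/1200 bp (n = 5,000 each); the A-EJ vs c-NHEJ signature (higher
mean MH, higher long-resection %, lower deletion/inversion ratio at
n = 5,000 per arm); and agreement of the pooled t with its closed form to
10⁻¹⁰ on 100 random groups.
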