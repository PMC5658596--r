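---
title: "Methods: IS-element detection, flank anatomy and comparative presence/absence"
author: "ISmobilome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IS-element detection, flank anatomy and comparative presence/absence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ISmobilome)
```

## The biological object

Insertion sequences (IS) are the smallest autonomous bacterial transposable
elements. The IS21-family elements this package models — exemplified by
ISS12 of the solvent-tolerant *Pseudomonas putida* S12 — are ~2.6 kb long
and carry two open reading frames, an integrase (transposase) and an ATPase
AAA helper, framed by ~150 bp terminal regions containing inverted repeats
(IRs). On insertion, 5–8 bp of host sequence at the target site is
duplicated, leaving a directed repeat (DR, the target-site duplication) on
each flank of the element; 7 bp is the dominant repeat length. Clean
excision — removal of the element plus exactly one DR copy — restores the
pre-insertion sequence, which is how a disrupted gene (in the motivating
system, the *srpA* inner-membrane component of the SrpABC solvent efflux
pump) can revert to a functional state under selection.

The package implements the computational side of a mobilome survey of such
a system: detect IS copies in an assembly, classify sequence variants,
extract DRs and IRs, classify each insertion's genomic context, call
per-site presence/absence against other genome versions or read sets, and
verify clean-excision revertants. A synthetic-genome generator with planted
ground truth makes every stage testable end to end.

## Coordinates

All coordinates are 1-based inclusive throughout — externally because the
survey tables the package mirrors print 1-based inclusive spans, and
internally because that is the native convention of R and of the
Bioconductor containers (IRanges/Biostrings) the package builds on. A
single convention removes the need for a converter layer. On circular
replicons a span may wrap the origin; such copies are stored with
`end < start` and `wraps = TRUE`, and all flank arithmetic goes through a
wrap-aware substring helper that rotates a linear copy on demand.

## Copy detection: seed-and-extend with offset voting

`find_is_copies()` searches both strands of a replicon for each reference
element:

1. **Seeding.** Exact k-mers of the reference (k = 13, taken every 2
   positions) are matched against the genome via a `Biostrings::PDict`
   index. Each hit implies a diagonal offset (genome position − reference
   position).
2. **Offset voting.** Hits are clustered by offset (tolerance 30 bp to
   absorb small indels); clusters with at least 3 supporting seeds become
   candidate loci. At 76% identity — the most diverged variant the family
   classification admits — the expected seed count for a full-length copy
   is ≈ 36, so candidate loss is negligible, while random 13-mer
   collisions almost never reach 3 consistent offsets.
3. **Verification.** The divergence model of the generator (and of the
   survey's variant table, which reports percent identity, not indel
   structure) is substitution-only, so a candidate is first verified by
   direct position-wise comparison of the projected reference span against
   the genome. A full-length copy is accepted when overall identity meets
   `min_identity` and both 40-bp end windows look element-like (identity
   ≥ 0.45, far above the ~0.25 random-flank expectation); its boundaries
   are then the *projected reference span* — the element anatomy places
   the DRs outside the copy, and projection makes boundary recovery exact
   even when the copy's terminal base happens to be substituted, which a
   maximal-scoring local alignment would trim. Partial (truncated) copies
   are reported as the maximal high-identity run of 31-bp windows.
4. **Indel fallback.** A candidate that fails the substitution-only check
   but whose best combined-offset identity bound still clears the
   threshold (an indel-bearing copy, e.g. the frameshifted variant) is
   rescued by local alignment (`pairwiseAlignment`, match 2 / mismatch −3
   / gap open 5 / extend 2) over the candidate window only. The fallback
   is skipped for loci already explained by a better direct hit, which is
   what keeps a multi-reference scan from re-aligning every locus against
   every indel-bearing reference.

Overlapping hits describing one locus (overlap > 50% of the shorter span)
keep the best identity; same-reference hits within 50 bp merge. Defaults
`min_identity = 0.7` and `min_coverage = 0.8` mirror the >70%
query-coverage BLAST-style cut-off such surveys use.

Monotonicity (raising `min_identity` never adds copies), strand symmetry,
and equivalence with full Smith–Waterman on small instances are asserted in
the test suite; the alignment there is the independent oracle, never the
code path under test.

## Variant classification

A copy takes the label of the reference with the highest identity: ≥ 99%
to a reference (or an established centroid) inherits that label; between
the 70% family floor and 99% founds a new centroid named after the nearest
reference; below the floor the copy is `unidentified`. The 99/70 cuts
cleanly separate the identity ladder of the motivating family
(100/96/84/76%). Equal-length comparisons use exact Hamming identity; for
unequal lengths a cheap shift-combined upper bound gates an overlap
alignment, computed only when that reference could actually win.

## ORF integrity

`check_orf_integrity()` projects each reference ORF onto the copy (identity
projection for equal lengths; alignment mapping otherwise) and calls
`intact` (start codon, terminal stop, no internal stop in the projected
frame), `frameshift` (net indel inside the ORF not divisible by 3),
`premature_stop` (in-frame internal stop — also the reported status for
the rare boundary lesion of a damaged start/stop codon without indel,
which the four-state vocabulary cannot express more precisely), or
`absent` (ORF region missing, e.g. truncated away). The reference pattern
of the frameshifted variant — integrase frameshifted, ATPase helper ORF
retained — is recovered from a planted 1-bp deletion, cross-checked
against a brute-force codon-scan oracle.

## Flank anatomy

**Directed repeats.** `detect_tsd()` reports the *largest* k in [4, 12]
whose k bases immediately 5′ of the copy equal the k bases immediately 3′
of it. Largest-k because survey tables report single maximal DRs; exact
matches only, because the duplication mechanism copies the target
literally (mismatched repeats are reported as `dr_len = 0`). kmax = 12
deliberately exceeds the observed 5–8 bp range so off-by-one bugs surface
as wrong lengths rather than silent truncation. A copy at a linear
replicon edge with insufficient flank is *flagged* (`dr_len = NA`) —
distinct from a genuine 0. The upper search bound is one of this package's
own definitions: the source survey does not state its search range.

**Inverted repeats.** `detect_irs()` enumerates all maximal
reverse-complement matches between the 5′ and 3′ terminal windows, per
diagonal, under a mismatch budget of `floor(frac × length)`; runs start
and end on matches and dominated runs are dropped. Results sort by length
descending, then leftmost — a deterministic tie-break.

**Flank conservation.** `flank_conservation()` computes per-position
information content, 2 − H in bits, over aligned equal-length flanks, with
a Miller–Madow small-sample correction of 3/(2 ln 2 · n) bits subtracted
per position (the expected positive bias of plug-in entropy with 4
symbols and n sequences; at n = 33 it is ≈ 0.066 bits, which is why
uncorrected IC of random flanks does not sit at zero). The verdict is
"no consensus" unless some 4-consecutive-position window exceeds a mean of
1.0 bit — a window an actual target-site motif (e.g. a conserved 4-mer,
IC ≈ 1.93 after correction) clears easily while uniform-random flanks
stay an order of magnitude below it.

## Insertion context

The insertion point for context purposes is the first base of the TSD —
the position actually interrupted in the ancestral gene model — not the
element midpoint. Code `a` (in-gene) applies when that point lies inside a
CDS or ncRNA feature (boundary-overlapping insertions included; ncRNA
features are code-a-eligible, consistent with how the survey tables
footnote ncRNA disruptions); code `c` (promoter) when it falls within 150
bp upstream of a feature's start on that feature's strand and inside no
feature; code `b` (intergenic) otherwise, reporting the two nearest
neighbours. The 150 bp promoter window is a package choice — surveys
rarely define "promoter region" — and is a logged, configurable
parameter. The three codes partition every insertion; census totals are
conserved by construction and property-tested.

## Presence/absence calling

For each site, three probes are built from the backbone genome: left
junction (flank + element head), right junction (element tail + flank),
and empty site (left flank joined to the right flank with exactly one DR
copy retained — the clean pre-insertion locus). Element interiors across
the whole backbone are masked before uniqueness checks, mirroring how a
re-assembly analysis must discard reads that map to any of the dozens of
near-identical element copies; a probe whose flank occurs more than once
in the masked backbone forces an `ambiguous` verdict.

A site is `present` when both junction probes are supported and the empty
probe is not, `absent` in the mirror case, and `ambiguous` on any
contradiction. Read support is exact full-probe substring containment
(either orientation), at least `min_support = 3` reads; assembly evidence
needs one occurrence. With 150-bp reads at 20× coverage a probe of length
2 × `probe_flank` is contained in ~Poisson(20 × (151 − 2·probe_flank)/150)
reads: at the package default `probe_flank = 30` that is ≈ 12.1 expected
supporting reads and a no-call probability of ~4 × 10⁻⁴ per probe, so a
33-site diff is expected to produce no spurious ambiguous calls. A 50-bp
flank (100-bp probes) would drop support to ≈ 6.8 and produce ~3% no-calls
per probe — measurably worse than the uniqueness it buys, since even a
60-bp probe is already astronomically unique in a bacterial replicon.
Error-free evidence can degrade a call only toward `ambiguous`, never to
the opposite definite verdict, and verdicts are invariant under read
order.

## Excision and revertant verification

`excise()` removes the element plus exactly one DR copy (the right-hand
copy; for exact repeats the choice is immaterial) after checking that both
flanks actually carry the stated repeat. Excision is the exact inverse of
insertion — byte equality with the ancestral sequence is property-tested
over hundreds of random cases.

`enumerate_restoring_excisions()` brute-forces every cut leaving 0, 1 or 2
DR copies plus every off-by-k boundary shift (|k| ≤ 3) and asks which
outcomes restore the disrupted gene. Restoration is asserted at the
**nucleotide** level: revertants are verified by sequencing, and a
sequence-identical gene is the observable. Protein-level equality is
reported per cut (`protein_restore`) but deliberately not used for
counting outcomes: a same-length cut shifted into the element replaces
junction bases with element bases, and in roughly a fifth of random
sequences that scar is synonymous — a protein-identical outcome that a
sequencer would still distinguish. Cuts shifted into the DR itself
reproduce the clean outcome byte-for-byte (both repeat copies are
identical), so outcomes are deduplicated by resulting sequence; for an
in-CDS insertion with a DR length not divisible by 3, exactly one
restoring outcome exists — the clean excision. A 6-bp repeat's
keep-both-copies cut is the instructive counterexample: frame-preserving
(scar ≡ 0 mod 3) but never sequence-restoring.

`verify_revertant()` anchors the site by its 5′ flank and compares the
revertant's local sequence (± 500 bp) against three constructed
hypotheses — clean excision, unchanged, and both-DR-copies-kept — in that
order, returning `other` for anything else (including anchor loss).

## The synthetic generator: what it emulates and what it does not

Defaults are the study conditions of the motivating system: replicon GC
61.8% (chromosome-like) or 57.8% (plasmid-like), realized by weighted base
sampling within ±1.5 percentage points; elements of 2596 bp with two
stop-free ORFs and a perfect terminal IR; TSD lengths drawn from the
observed census 7:24/33, 6:4/33, 8:4/33, 5:1/33; variants at 84% (C-like)
and 76–77% with an explicit integrase frameshift (D-like), produced by
uniform random substitution; both orientations; circular or linear
replicons; truncated copies on request. Reads are error-free uniform
substrings of either strand, crossing the origin on circular replicons.

Deliberate simplifications: substitutions are placed uniformly, so
diverged variant copies generally do *not* retain intact reading frames or
IRs the way a real descendant lineage under selection might; there is no
sequencing-error or coverage-bias model, no repeat content beyond the
planted elements, and gene annotations are a uniform tile of 900-bp ORFs
rather than an operon structure. Passing tests therefore demonstrate
correctness of the *logic* (coordinates, repeat arithmetic, probe algebra,
census conservation) under a clean substitution-only world, not robustness
to sequencing artefacts, nested elements or repeat-rich genomes.

## Problem sizes and determinism

The shipped test suite exercises 20 random fixtures of 50–200 kb with 5–40
copies each for detection recovery, 500 random insert/excise round trips,
paired 35-kb trios with 20× read sets for presence/absence, and
100-case lesion panels for ORF integrity — sizes chosen so the whole suite
runs in a couple of minutes on one core while keeping every census number
at the survey's full scale (33 sites). Every stochastic step routes
through explicit seeds; regenerating any fixture from its seed is
bit-identical, and `with_seed()` restores the caller's RNG state so
library calls never perturb user randomness.

## Known limitations

* De novo IS discovery (profile-based, ISEScan-style) is out of scope:
  detection is strictly reference-based.
* GenBank annotation parsing is not provided; annotations enter as GFF3 or
  plain tables.
* The `unidentified` label is a threshold bucket, not a claim about any
  particular real element family.
* Two short spans in the packaged survey table (~1195 bp) are loaded as
  printed; whether the underlying elements are truncated copies is not a
  claim this package makes, though the generator supports planting
  truncated copies to exercise that code path.
* Excision rates, selection dynamics and transposition mechanism are
  explicitly not modelled; the package verifies sequence outcomes only.
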