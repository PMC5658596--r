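# ISmobilome

Reference-based insertion-sequence (IS) mobilome analysis for bacterial
genomes, built around the anatomy of IS21-family elements such as ISS12 of
the solvent-tolerant *Pseudomonas putida* S12: a ~2.6 kb element carrying
an integrase and an ATPase AAA helper ORF, terminal inverted repeats (IR),
and a 5–8 bp target-site duplication (directed repeat, DR) left on both
flanks of every insertion.

The package is for genome analysts characterizing mobile-element dynamics
between genome versions of one strain — the setting where a re-sequenced
isolate turns out to carry dozens of new IS copies, one of which disrupts
a phenotype-critical gene (in the motivating system, *srpA* of the SrpABC
solvent efflux pump), and where revertants arise by clean excision. It
provides:

* **Detection** — `find_is_copies()`: seed-and-extend scanning (exact
  k-mer seeds, offset voting, substitution-model verification with a local
  alignment fallback for indel-bearing copies) of both strands, wrap-aware
  on circular replicons; variant labelling by nearest reference with a 99%
  same-variant / 70% family-floor rule (`classify_variant()`); per-copy
  ORF-integrity calls `intact` / `frameshift` / `premature_stop` /
  `absent` (`check_orf_integrity()`).
* **Flank anatomy** — `detect_tsd()` (largest exact repeat k ∈ [4, 12]
  flanking a copy), `detect_irs()` (maximal reverse-complement terminal
  matches under a mismatch budget), `flank_conservation()` (per-position
  information content, 2 − H bits with Miller–Madow correction, and a
  consensus/no-consensus verdict for insertion-site preference).
* **Context** — `classify_context()`: each insertion point (first base of
  the TSD) is in-gene (a), intergenic (b) or promoter (c, within 150 bp
  upstream of a start); censuses via `summarize_contexts()`.
* **Comparative presence/absence** — `build_probes()` /
  `call_presence()` / `diff_mobilomes()`: junction and empty-site probes
  (the empty-site probe retains exactly one DR copy), uniqueness checking
  against the element-masked backbone, and present/absent/ambiguous
  verdicts from read sets or assemblies.
* **Excision** — `excise()` (element + exactly one DR copy),
  `enumerate_restoring_excisions()` (exhaustive proof that only the clean
  cut restores an in-frame gene), `verify_revertant()`.
* **Synthetic truth** — `make_genome_fixture()`, `make_reference_set()`,
  `make_mobilome_trio()`, `simulate_reads()`: replicons at chromosome-like
  (61.8%) or plasmid-like (57.8%) GC, planted copies at 100/84/76%
  identity in both orientations, TSD lengths drawn from the observed
  7:24/33, 6:4/33, 8:4/33, 5:1/33 census, truncated copies, and
  ancestral/derived/revertant trios — all bit-reproducible from a seed.

A transcribed 33-site insertion survey table of *P. putida* S12/A ships in
`inst/extdata/` and loads with `load_insertion_table()`.

## Worked example

```r
library(ISmobilome)

# the packaged survey table: 33 ISS12-family insertion sites
rec <- load_insertion_table(system.file(
  "extdata", "pputida_S12A_insertion_sites.tsv", package = "ISmobilome"))
mobilome_census(rec)$variants
#>   variant     n
#> 1 ISS12      28
#> 2 ISS12_C     4
#> 3 ISS12_D     1
mobilome_census(rec)$dr_hist
#>   dr_len     n
#> 1      5     1
#> 2      6     4
#> 3      7    24
#> 4      8     4
summarize_contexts(rec)
#> <context_census> 33 insertions: 25 in-gene (a), 4 intergenic (b), 4 promoter (c)

# synthetic end-to-end: plant, detect, extract repeats
refs <- make_reference_set(1)
fx <- make_genome_fixture(2, length = 50000, n_copies = 6, refs = refs,
                          circular = FALSE)
cp <- find_is_copies(fx$mutated, refs, replicon = "demo")
cp[, c("copy_id", "start", "end", "orientation", "is_id", "identity")]
#>   copy_id   start   end orientation is_id   identity
#> 1 demo_c001 21616 24211 Forward     ISS12_A        1
#> 2 demo_c002 26511 29106 Reverse     ISS12_A        1
#> 3 demo_c003 42956 45551 Reverse     ISS12_A        1
#> ...
detect_tsds(fx$mutated, cp)[, c("copy_id", "dr_len", "dr_seq")]
#>   copy_id   dr_len dr_seq
#> 1 demo_c001      7 CGTAAAG
#> 2 demo_c002      8 CAGCCGAA
#> 3 demo_c003      6 AATCCG
#> ...
```

The detected spans match the planted truth exactly (`fx$truth`), each
`dr_seq` is the host 5–8-mer duplicated at insertion, and
`excise(fx$mutated, start, end, dr_len)` inverts each insertion
byte-for-byte.

## Analysis workflow

`analysis/01_simulate.R` … `analysis/07_report.R` run the whole study
pipeline on a simulated two-replicon system (a 120 kb chromosome-like and
a 60 kb plasmid-like replicon, 33 planted copies with the survey's variant
and repeat-length census, one designated srpA-like disruption): simulate →
detect → repeats/IRs/flank-IC → contexts → presence/absence against a
"previous" genome → clean excision and revertant verdicts → final report
tables. Run them in order from the repository root; outputs land under
`results/`.

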