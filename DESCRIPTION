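Package: ISmobilome
Title: Insertion-Sequence Mobilome Analysis for Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterizes insertion-sequence (IS) copies in
    bacterial genome assemblies. Provides reference-based IS copy detection
    with orientation, identity and variant classification; target-site
    duplication (directed repeat) and terminal inverted repeat extraction;
    ORF-integrity calls (frameshift, premature stop, truncation) within each
    copy; insertion-context classification against genome annotations;
    junction-probe presence/absence calling of each insertion site in a
    second assembly or read set; and verification of clean excision events
    that restore a disrupted gene. Ships a synthetic-genome generator with
    planted insertions (ground truth attached) so every stage is testable
    end to end, plus a transcribed insertion-site table from an IS21-family
    mobilome survey of the solvent-tolerant Pseudomonas putida S12.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    tibble
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
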