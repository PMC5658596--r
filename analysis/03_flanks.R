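# Stage 3 — extract the directed repeat (target-site duplication) of every
# detected copy, the terminal inverted repeats of each reference variant,
# and test the insertion-site flanks for a conserved consensus.

source("analysis/00_config.R")

genomes <- read_fasta(rpath("genome.fasta"))
copies <- tibble::as_tibble(utils::read.delim(rpath("copies.tsv")))
truth <- read_truth()

tsds <- list()
for (rn in names(genomes)) {
  cp <- copies[copies$replicon == rn, ]
  tsds[[rn]] <- detect_tsds(genomes[[rn]], cp,
                            circular = REPLICONS[[rn]]$circular)
}
tsds <- do.call(rbind, tsds)
utils::write.table(tsds, rpath("tsds.tsv"), sep = "\t", quote = FALSE,
                   row.names = FALSE)

hist <- dr_length_histogram(tsds)
message("DR length census: ",
        paste(sprintf("%d bp x %d", hist$dr_len, hist$n), collapse = ", "))
planted <- truth[order(truth$replicon, truth$start), ]
tsds_ord <- tsds[order(copies$replicon, copies$start), ]
message("planted repeats recovered: ",
        sum(tsds_ord$dr_len == planted$tsd_len), "/", nrow(planted))

# terminal inverted repeats of each reference variant
refs <- make_reference_set(SEED)
for (r in refs) {
  irs <- detect_irs(r$sequence, window = 150, min_len = 12,
                    max_mismatch_frac = 0.1)
  top <- if (nrow(irs) > 0) sprintf("%d bp (%d mismatches)",
                                    irs$length[1], irs$mismatches[1])
         else "none"
  message(r$id, ": longest terminal IR ", top)
}

# flank consensus test over all insertion sites (30 bp upstream flanks in
# the ancestral genomes, i.e. the sequence the element actually targeted)
anc <- read_fasta(rpath("ancestral.fasta"))
flanks <- vapply(seq_len(nrow(truth)), function(i) {
  substr(anc[[truth$replicon[i]]], truth$target_pos[i] - 30,
         truth$target_pos[i] - 1)
}, character(1))
fc <- flank_conservation(flanks)
message(sprintf("insertion-site flanks (n=%d): %s (mean IC %.3f bits)",
                length(flanks), fc$verdict, mean(fc$ic)))
utils::write.table(
  data.frame(position = seq_along(fc$ic), ic_bits = fc$ic),
  rpath("flank_information_content.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
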