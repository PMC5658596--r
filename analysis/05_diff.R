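# Stage 5 — presence/absence of every insertion site in a "previous"
# genome (carrying only a subset of the insertions), called from simulated
# error-free reads via junction and empty-site probes.

source("analysis/00_config.R")

genomes <- read_fasta(rpath("genome.fasta"))
anc <- read_fasta(rpath("ancestral.fasta"))
truth <- read_truth()
copies <- tibble::as_tibble(utils::read.delim(rpath("copies.tsv")))
refs <- make_reference_set(SEED)

set.seed(SEED + 50)
calls_all <- list()
for (rn in names(genomes)) {
  tr <- truth[truth$replicon == rn, ]
  tr <- tr[order(tr$start), ]
  # the "previous" genome carries a fixed subset of the insertions
  prev_idx <- sort(sample(nrow(tr), N_PREVIOUS[[rn]]))
  tr$in_previous <- seq_len(nrow(tr)) %in% prev_idx
  prev <- plant_insertions(
    anc[[rn]],
    tibble::tibble(target_pos = tr$target_pos[prev_idx],
                   element = lapply(tr$is_id[prev_idx],
                                    function(v) refs[[v]]$sequence),
                   orientation = tr$orientation[prev_idx],
                   tsd_len = tr$tsd_len[prev_idx],
                   is_id = tr$is_id[prev_idx]))
  reads <- simulate_reads(prev$genome, read_len = 150, coverage = 20,
                          seed = SEED + 60 + match(rn, names(genomes)),
                          circular = REPLICONS[[rn]]$circular)
  tr$copy_id <- copies$copy_id[copies$replicon == rn]
  dm <- diff_mobilomes(genomes[[rn]], tr, list(previous = reads),
                       circular = REPLICONS[[rn]]$circular)
  calls <- dm$calls
  calls$replicon <- rn
  calls$in_previous_truth <- tr$in_previous[match(calls$copy_id, tr$copy_id)]
  calls_all[[rn]] <- calls
  ok <- all(calls$verdict == ifelse(tr$in_previous, "present", "absent"))
  message(sprintf(
    "%s: %d/%d sites unique to the resequenced genome; calls %s truth", rn,
    length(dm$unique_to_backbone), nrow(tr),
    if (ok) "match" else "DIVERGE from"))
}
calls <- do.call(rbind, calls_all)
utils::write.table(calls, rpath("presence_calls.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("presence split: ", sum(calls$verdict == "present"), " present / ",
        sum(calls$verdict == "absent"), " absent")
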