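# Stage 1 — simulate the study system: a chromosome-like and a
# megaplasmid-like replicon with 33 planted IS copies (known ground truth),
# a reference element family (primary + two diverged variants), and gene
# annotations. One in-gene plasmid insertion is designated the srpA-like
# solvent-pump disruption for the excision stage.

source("analysis/00_config.R")

refs <- make_reference_set(SEED)
message("reference family: ",
        paste(vapply(refs, function(r) sprintf("%s (%d bp)", r$id,
                                               nchar(r$sequence)),
                     character(1)), collapse = ", "))

truth_all <- list()
ann_all <- list()
seqs_anc <- character(0)
seqs_mut <- character(0)

for (rn in names(REPLICONS)) {
  rc <- REPLICONS[[rn]]
  # shuffle the per-copy attributes reproducibly
  fx <- make_genome_fixture(
    SEED + match(rn, names(REPLICONS)), length = rc$length, gc = rc$gc,
    circular = rc$circular, n_copies = rc$n_copies, refs = refs,
    variants = sample(rc$variants), tsd_lens = sample(rc$tsd_lens),
    name = rn)
  truth_all[[rn]] <- fx$truth
  ann <- fx$annotations
  ann$replicon <- rn
  ann_all[[rn]] <- ann
  seqs_anc[rn] <- fx$ancestral
  seqs_mut[rn] <- fx$mutated
  message(sprintf("%s: %d bp (GC %.3f), %d planted copies", rn, rc$length,
                  gc_content(fx$ancestral), rc$n_copies))
}

truth <- do.call(rbind, truth_all)
ann <- do.call(rbind, ann_all)

# designate the first in-gene plasmid copy as the srpA-like disruption
plas_truth <- truth[truth$replicon == "plasmid", ]
ctx <- classify_contexts(plas_truth$target_pos, ann_all$plasmid)
in_gene <- which(ctx$context_code == "a")
srp_row <- plas_truth[in_gene[1], ]
srp_gene <- ctx$affected[in_gene[1]]
ann$product[ann$replicon == "plasmid" & ann$feature_id == srp_gene] <-
  "Solvent resistance pump (SrpA)"
truth$srp_like <- truth$replicon == "plasmid" &
  truth$target_pos == srp_row$target_pos
message("srpA-like disruption: plasmid gene ", srp_gene,
        " at insertion point ", srp_row$target_pos)

write_fasta(seqs_anc, rpath("ancestral.fasta"))
write_fasta(seqs_mut, rpath("genome.fasta"))
write_fasta(stats::setNames(vapply(refs, function(r) r$sequence, character(1)),
                            names(refs)), rpath("is_references.fasta"))
for (rn in names(REPLICONS)) {
  write_annotation_gff3(ann[ann$replicon == rn,
                            setdiff(names(ann), "replicon")],
                        rpath(paste0("annotation_", rn, ".gff3")), seqid = rn)
}
utils::write.table(truth, rpath("truth.tsv"), sep = "\t", quote = FALSE,
                   row.names = FALSE)
message("wrote genomes, annotations, references and truth under results/")
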