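# Stage 7 — assemble the survey-style mobilome report for the simulated
# genomes (one row per copy: variant, span, orientation, presence, DR,
# context) and recompute the census of the packaged real-survey table for
# comparison.

source("analysis/00_config.R")

copies <- tibble::as_tibble(utils::read.delim(rpath("copies.tsv")))
tsds <- tibble::as_tibble(utils::read.delim(rpath("tsds.tsv")))
ctx <- tibble::as_tibble(utils::read.delim(rpath("contexts.tsv")))
calls <- tibble::as_tibble(utils::read.delim(rpath("presence_calls.tsv")))
tsds$dr_seq[is.na(tsds$dr_seq)] <- ""

diffs <- list(
  matrix = tibble::tibble(copy_id = copies$copy_id),
  unique_to_backbone = calls$copy_id[calls$verdict == "absent"]
)
rep <- render_mobilome_report(copies, tsds, ctx, diffs = diffs)

utils::write.table(rep$table, rpath("mobilome_report.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(rep$variants, rpath("variant_census.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(rep$dr_hist, rpath("dr_length_histogram.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

message("simulated mobilome: ", nrow(rep$table), " copies")
message("variants: ", paste(rep$variants$variant, rep$variants$n,
                            sep = "=", collapse = ", "))
message("DR lengths: ", paste(rep$dr_hist$dr_len, rep$dr_hist$n,
                              sep = ":", collapse = ", "))
message("presence in previous genome: ",
        paste(names(rep$presence), rep$presence, sep = "=", collapse = ", "))

# census of the packaged real-survey table, for side-by-side comparison
rec <- load_insertion_table(system.file(
  "extdata", "pputida_S12A_insertion_sites.tsv", package = "ISmobilome"))
cs <- mobilome_census(rec)
message(sprintf(
  "real survey table: %d insertions; %s; DR %s; %d in-gene (%s); %d/%d present/absent in previous sequences",
  cs$n_total,
  paste(cs$variants$variant, cs$variants$n, sep = "=", collapse = ", "),
  paste(cs$dr_hist$dr_len, cs$dr_hist$n, sep = ":", collapse = ", "),
  cs$contexts$n_in_gene,
  paste(names(cs$contexts$in_gene), cs$contexts$in_gene, sep = "=",
        collapse = ", "),
  cs$presence["present"], cs$presence["absent"]))
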