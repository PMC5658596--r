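# Stage 4 — classify each insertion against the gene annotation: inside a
# gene (a), intergenic (b) or in a promoter region (c), and census the
# disruptions per replicon.

source("analysis/00_config.R")

truth <- read_truth()
copies <- tibble::as_tibble(utils::read.delim(rpath("copies.tsv")))

ctx_all <- list()
for (rn in names(REPLICONS)) {
  ann <- read_annotation_gff3(rpath(paste0("annotation_", rn, ".gff3")))
  tr <- truth[truth$replicon == rn, ]
  tr <- tr[order(tr$start), ]
  ids <- copies$copy_id[copies$replicon == rn]
  ctx <- classify_contexts(tr$target_pos, ann, ids = ids)
  ctx$replicon <- rn
  ctx_all[[rn]] <- ctx
}
ctx <- do.call(rbind, ctx_all)
utils::write.table(ctx, rpath("contexts.tsv"), sep = "\t", quote = FALSE,
                   row.names = FALSE)

census <- summarize_contexts(tibble::tibble(context_code = ctx$context_code,
                                            replicon = ctx$replicon))
message(sprintf("contexts: %d in-gene (a), %d intergenic (b), %d promoter (c)",
                census$by_code["a"], census$by_code["b"], census$by_code["c"]))
message("in-gene disruptions per replicon: ",
        paste(names(census$in_gene), census$in_gene, sep = "=",
              collapse = ", "))
srp <- ctx[grepl("SrpA", ctx$context_text), ]
if (nrow(srp) > 0)
  message("solvent-pump disruption confirmed at copy ", srp$id[1])
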