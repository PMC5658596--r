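# Shared fixtures, built once per test session (the reference set warms the
# k-mer index cache, so detection calls after the first are fast).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Full-size reference set (2596 bp primary + 84% / 77%-frameshift variants).
test_refs <- function() cached("refs2596", make_reference_set(101))

# Small reference set for alignment-heavy loops.
test_refs_small <- function() cached("refs1200", make_reference_set(202, length = 1200))

# Standard linear mid-size fixture with mixed variants.
test_fixture <- function() {
  cached("fx_linear", make_genome_fixture(
    301, length = 60000, circular = FALSE, n_copies = 8, refs = test_refs(),
    variants = c("ISS12_A", "ISS12_A", "ISS12_C", "ISS12_A", "ISS12_D",
                 "ISS12_A", "ISS12_C", "ISS12_A")))
}

table3_path <- function() {
  system.file("extdata", "pputida_S12A_insertion_sites.tsv",
              package = "ISmobilome")
}

# A genome with one known gene and one IS copy planted strictly inside it;
# used by excision and context tests.
make_gene_case <- function(seed, elem_len = 300, tsd_len = 7,
                           genome_len = 3000, gene_len = 900,
                           strand = "+") {
  with_seed <- ISmobilome:::with_seed
  with_seed(seed, {
    anc <- random_dna(genome_len, gc = 0.6)
    gene_start <- 501
    gene_end <- gene_start + gene_len - 1
    orf <- paste0("ATG", ISmobilome:::sample_nonstop_codons(gene_len / 3 - 2, 0.6), "TAA")
    gene_nt <- orf
    if (strand == "-") orf <- revcomp(orf)
    anc <- ISmobilome:::str_replace_range(anc, gene_start, gene_end, orf)
    element <- random_dna(elem_len, gc = 0.55)
    # insertion point strictly inside the gene, TSD fully inside too
    site <- sample((gene_start + 30):(gene_end - 30 - tsd_len), 1)
    pl <- plant_insertion(anc, site, element, "Forward", tsd_len)
    list(ancestral = anc, mutated = pl$genome, insertion = pl$insertion,
         gene_start = gene_start, gene_end_anc = gene_end,
         gene_end_mut = gene_end + elem_len + tsd_len,
         gene_nt = gene_nt, strand = strand,
         ref_protein = ISmobilome:::translate_to_stop(gene_nt),
         element = element, site = site, tsd_len = tsd_len)
  })
}
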