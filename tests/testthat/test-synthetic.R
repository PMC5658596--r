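test_that("reference elements are deterministic, IR-flanked and stop-free", {
  ref1 <- make_is_reference(11, length = 2596, ir_len = 20)
  ref2 <- make_is_reference(11, length = 2596, ir_len = 20)
  expect_identical(ref1$sequence, ref2$sequence)
  expect_equal(nchar(ref1$sequence), 2596)

  # first 20 bp reverse-complement-match the last 20 bp
  expect_identical(substr(ref1$sequence, 1, 20),
                   revcomp(substr(ref1$sequence, 2577, 2596)))

  # independent brute-force codon scan of both ORFs: no internal stops,
  # proper start and stop codons
  for (i in 1:2) {
    orf <- ref1$orf_models[i, ]
    seg <- substr(ref1$sequence, orf$start, orf$end)
    codons <- substring(seg, seq(1, nchar(seg) - 2, 3), seq(3, nchar(seg), 3))
    expect_identical(codons[1], "ATG")
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
    # ORFs stay clear of the terminal windows
    expect_gt(orf$start, ref1$terminal_window)
    expect_lte(orf$end, 2596 - ref1$terminal_window)
  }
  expect_error(make_is_reference(1, length = 700,
                                 orf_layout = list(orf1_len = 600,
                                                   orf2_len = 600, gap = 10)),
               "infeasible")
})

test_that("mutate_to_identity hits the target identity with substitutions only", {
  ref <- test_refs()$ISS12_A
  expect_identical(mutate_to_identity(ref, 1.0, seed = 1), ref$sequence)

  m84 <- mutate_to_identity(ref, 0.84, seed = 7)
  expect_equal(nchar(m84), nchar(ref$sequence))
  # independent position-wise mismatch count
  mm <- sum(strsplit(m84, "")[[1]] != strsplit(ref$sequence, "")[[1]])
  ident <- 1 - mm / nchar(ref$sequence)
  expect_gte(ident, 0.83)
  expect_lte(ident, 0.85)

  m76 <- mutate_to_identity(ref, 0.76, seed = 8)
  mm76 <- sum(strsplit(m76, "")[[1]] != strsplit(ref$sequence, "")[[1]])
  expect_equal(1 - mm76 / nchar(ref$sequence), 0.76, tolerance = 0.011)

  expect_error(mutate_to_identity(ref, 0.4), "identity")
  expect_error(mutate_to_identity(ref, 1.2), "identity")
})

test_that("random replicons hit their GC target", {
  g1 <- random_dna(50000, gc = 0.618, seed = 3)
  g2 <- random_dna(50000, gc = 0.578, seed = 3)
  expect_lt(abs(gc_content(g1) - 0.618), 0.015)
  expect_lt(abs(gc_content(g2) - 0.578), 0.015)
  fx <- make_genome_fixture(77, length = 30000, gc = 0.618, n_copies = 0)
  expect_lt(abs(gc_content(fx$ancestral) - 0.618), 0.015)
})

test_that("plant_insertion duplicates the target site on both flanks", {
  g <- random_dna(5000, seed = 21)
  el <- random_dna(400, seed = 22)

  pl <- plant_insertion(g, 2000, el, "Forward", tsd_len = 7)
  ins <- pl$insertion
  expect_equal(nchar(pl$genome), 5000 + 400 + 7)
  tsd <- substr(g, 2000, 2006)
  expect_identical(ins$tsd_seq, tsd)
  # both flanks of the element carry the same 7-mer
  expect_identical(substr(pl$genome, ins$start - 7, ins$start - 1), tsd)
  expect_identical(substr(pl$genome, ins$end + 1, ins$end + 7), tsd)
  expect_identical(substr(pl$genome, ins$start, ins$end), el)

  # zero-length TSD: pure insertion, flanks unchanged
  pl0 <- plant_insertion(g, 2000, el, "Forward", tsd_len = 0)
  expect_equal(nchar(pl0$genome), 5400)
  expect_identical(substr(pl0$genome, 1, 1999), substr(g, 1, 1999))
  expect_identical(substr(pl0$genome, 2400, 5400), substr(g, 2000, 5000))

  # reverse orientation inserts the reverse complement
  plr <- plant_insertion(g, 2000, el, "Reverse", tsd_len = 7)
  expect_identical(substr(plr$genome, plr$insertion$start, plr$insertion$end),
                   revcomp(el))

  # planting inside an existing element is rejected
  expect_error(
    plant_insertion(pl$genome, ins$start + 50, el, existing = ins),
    "inside a previously planted")
})

test_that("fixtures are reproducible and truth re-derives the mutated genome", {
  fx1 <- make_genome_fixture(55, length = 20000, n_copies = 4)
  fx2 <- make_genome_fixture(55, length = 20000, n_copies = 4)
  expect_identical(fx1$mutated, fx2$mutated)
  expect_identical(fx1$truth, fx2$truth)

  fx <- test_fixture()
  sites <- tibble::tibble(
    target_pos = fx$truth$target_pos,
    element = lapply(fx$truth$is_id, function(v) fx$refs[[v]]$sequence),
    orientation = fx$truth$orientation,
    tsd_len = fx$truth$tsd_len,
    is_id = fx$truth$is_id)
  re <- plant_insertions(fx$ancestral, sites)
  expect_identical(re$genome, fx$mutated)
  expect_identical(re$truth$start, fx$truth$start)

  # every planted copy's flanks in the mutated genome carry the TSD
  for (i in seq_len(nrow(fx$truth))) {
    tr <- fx$truth[i, ]
    if (tr$tsd_len == 0) next
    expect_identical(substr(fx$mutated, tr$start - tr$tsd_len, tr$start - 1),
                     tr$tsd_seq)
    expect_identical(substr(fx$mutated, tr$end + 1, tr$end + tr$tsd_len),
                     tr$tsd_seq)
  }
})

test_that("simulated reads are exact genome substrings at the expected depth", {
  g <- random_dna(50000, seed = 31)
  reads <- simulate_reads(g, read_len = 100, coverage = 20, seed = 32)
  expect_lt(abs(length(reads) - 10000) / 10000, 0.2)

  # substring-check oracle on a sample of reads (both strands allowed)
  g_rc <- revcomp(g)
  for (r in reads[seq(1, length(reads), by = 200)]) {
    expect_true(grepl(r, g, fixed = TRUE) || grepl(r, g_rc, fixed = TRUE))
  }

  # circular sampling crosses the origin
  gc_small <- random_dna(4000, seed = 33)
  rc <- simulate_reads(gc_small, read_len = 200, coverage = 20, seed = 34,
                       circular = TRUE)
  doubled <- paste0(gc_small, gc_small)
  junction <- substr(doubled, 4000 - 150, 4000 + 150)
  spans_origin <- vapply(rc, function(r) {
    (!grepl(r, gc_small, fixed = TRUE) &&
       !grepl(r, revcomp(gc_small), fixed = TRUE)) &&
      (grepl(r, doubled, fixed = TRUE) ||
         grepl(r, revcomp(doubled), fixed = TRUE))
  }, logical(1))
  expect_gt(sum(spans_origin), 0)
  expect_true(all(vapply(rc, function(r)
    grepl(r, doubled, fixed = TRUE) || grepl(r, revcomp(doubled), fixed = TRUE),
    logical(1))))

  expect_error(simulate_reads(substr(g, 1, 50), read_len = 100), "shorter")
})
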