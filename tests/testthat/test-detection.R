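test_that("planted copies are recovered exactly, with variants and orientations", {
  fx <- test_fixture()
  cp <- find_is_copies(fx$mutated, fx$refs, replicon = fx$name)
  tr <- fx$truth[order(fx$truth$start), ]
  expect_equal(nrow(cp), nrow(tr))
  expect_equal(cp$start, tr$start)
  expect_equal(cp$end, tr$end)
  expect_identical(cp$orientation, tr$orientation)
  expect_identical(cp$is_id, tr$is_id)
  # exact copies of their references
  expect_true(all(cp$identity >= 0.999))
  expect_true(all(cp$coverage >= 0.99))
})

test_that("empty and element-free genomes yield empty results; bad refs error", {
  refs <- test_refs()
  expect_equal(nrow(find_is_copies("", refs)), 0)
  clean <- random_dna(20000, seed = 9)
  expect_equal(nrow(find_is_copies(clean, refs)), 0)
  expect_error(find_is_copies(clean, list(tiny = random_dna(60, seed = 1))),
               "degenerate")
  expect_error(find_is_copies(clean, list()), "non-empty")
  expect_error(find_is_copies(clean, refs, min_identity = 0), "min_identity")
})

test_that("a reverse-planted copy reports Reverse with the forward identity", {
  refs <- test_refs()
  g <- random_dna(12000, seed = 41)
  el <- mutate_to_identity(refs$ISS12_A, 0.9, seed = 42)
  fw <- plant_insertion(g, 6000, el, "Forward", 7)
  rv <- plant_insertion(g, 6000, el, "Reverse", 7)
  cp_f <- find_is_copies(fw$genome, refs["ISS12_A"], classify = FALSE)
  cp_r <- find_is_copies(rv$genome, refs["ISS12_A"], classify = FALSE)
  expect_equal(nrow(cp_f), 1)
  expect_equal(nrow(cp_r), 1)
  expect_identical(cp_f$orientation, "Forward")
  expect_identical(cp_r$orientation, "Reverse")
  expect_equal(cp_r$identity, cp_f$identity, tolerance = 1e-12)
  expect_equal(cp_r$start, cp_f$start)
})

test_that("detection is strand-symmetric", {
  fx <- test_fixture()
  len <- nchar(fx$mutated)
  cp <- find_is_copies(fx$mutated, fx$refs, replicon = "fwd")
  cp_rc <- find_is_copies(revcomp(fx$mutated), fx$refs, replicon = "rc")
  expect_equal(nrow(cp_rc), nrow(cp))
  # mirrored coordinates and flipped orientations
  expect_equal(sort(len - cp$end + 1), sort(cp_rc$start))
  expect_equal(sort(len - cp$start + 1), sort(cp_rc$end))
  flipped <- ifelse(cp$orientation == "Forward", "Reverse", "Forward")
  expect_identical(rev(cp_rc$orientation), flipped)
})

test_that("raising min_identity never increases the number of copies", {
  fx <- test_fixture()
  # single-reference scan so the thresholds bite on the diverged variants
  thresholds <- c(0.7, 0.8, 0.9, 0.995)
  counts <- vapply(thresholds, function(t)
    nrow(find_is_copies(fx$mutated, fx$refs["ISS12_A"], min_identity = t,
                        classify = FALSE)), integer(1))
  expect_true(all(diff(counts) <= 0))
  # at 0.995 only the exact primary copies remain
  expect_equal(counts[4], sum(fx$truth$is_id == "ISS12_A"))
  # the full reference set keeps all copies even at a strict threshold
  # (every copy is exact against its own variant reference)
  expect_equal(nrow(find_is_copies(fx$mutated, fx$refs, min_identity = 0.995)),
               nrow(fx$truth))
})

test_that("copies wrapping a circular origin are found with wrapped coordinates", {
  refs <- test_refs()
  g <- random_dna(20000, seed = 51)
  pl <- plant_insertion(g, 10000, refs$ISS12_A, "Forward", 7)
  # rotate so that the copy spans the origin
  mid <- pl$insertion$start + 1200
  rot <- ISmobilome:::rotate_seq(pl$genome, mid)
  cp <- find_is_copies(rot, refs["ISS12_A"], circular = TRUE)
  expect_equal(nrow(cp), 1)
  expect_true(cp$wraps)
  expect_lt(cp$end, cp$start)
  # the wrapped span still covers the full element
  len <- nchar(rot)
  expect_equal((len - cp$start + 1) + cp$end, 2596)
  expect_identical(copy_sequence(rot, cp[1, ], circular = TRUE),
                   refs$ISS12_A$sequence)
})

test_that("seed-and-extend agrees with full local alignment on small instances", {
  refs <- test_refs_small()
  g <- random_dna(8000, seed = 61)
  el <- mutate_to_identity(refs$ISS12_A, 0.85, seed = 62)
  pl <- plant_insertion(g, 4000, el, "Forward", 7)
  cp <- find_is_copies(pl$genome, refs["ISS12_A"], classify = FALSE)
  expect_equal(nrow(cp), 1)
  # independent oracle: Smith-Waterman of the reference against the genome
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(refs$ISS12_A$sequence),
    Biostrings::DNAString(pl$genome),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3),
    gapOpening = 5, gapExtension = 2)
  sw_start <- aln@subject@range@start
  sw_end <- sw_start + aln@subject@range@width - 1L
  # Smith-Waterman trims terminal mismatches that the projected reference
  # span retains; the two must agree up to those trimmed runs
  expect_lte(cp$start, sw_start)
  expect_gte(cp$end, sw_end)
  expect_lte(sw_start - cp$start, 10)
  expect_lte(cp$end - sw_end, 10)
  expect_equal(cp$identity, Biostrings::pid(aln, "PID1") / 100,
               tolerance = 0.01)
})

test_that("truncated copies are reported with partial coverage", {
  refs <- test_refs()
  g <- random_dna(15000, seed = 71)
  pl <- plant_insertion(g, 7000, refs$ISS12_A, "Forward", 7,
                        truncation = list(keep = 0.46, end = "left"))
  cp <- find_is_copies(pl$genome, refs["ISS12_A"], min_coverage = 0.3,
                       classify = FALSE)
  expect_equal(nrow(cp), 1)
  expect_lt(cp$coverage, 0.55)
  expect_gt(cp$coverage, 0.4)
  # boundaries of a partial copy are recovered to within a window's width
  expect_lte(abs(cp$start - pl$insertion$start), 20)
  expect_lte(abs(cp$end - pl$insertion$end), 20)
})

test_that("variant classification follows best-reference and floor rules", {
  refs <- test_refs()
  primary <- refs$ISS12_A$sequence
  expect_identical(classify_variant(primary, refs)$label, "ISS12_A")
  expect_equal(classify_variant(primary, refs)$identity, 1.0)

  # an 84% copy takes the secondary label, not the primary
  c_copy <- refs$ISS12_C$sequence
  cl <- classify_variant(c_copy, refs)
  expect_identical(cl$label, "ISS12_C")

  # far below the family floor: unidentified
  junk <- random_dna(2596, seed = 81)
  expect_identical(classify_variant(junk, refs)$label, "unidentified")

  # between floor and same-variant: founds a new centroid
  mid <- mutate_to_identity(refs$ISS12_A, 0.9, seed = 82)
  cl_mid <- classify_variant(mid, refs)
  expect_match(cl_mid$label, "^ISS12_A_v")
  expect_equal(cl_mid$identity, 0.9, tolerance = 0.011)
})

test_that("ORF integrity calls match planted lesions and a translation oracle", {
  refs <- test_refs()
  ref <- refs$ISS12_A

  expect_identical(unname(check_orf_integrity(ref$sequence, ref)),
                   c("intact", "intact"))

  # the frameshifted-variant pattern: 1-bp deletion in the integrase ORF,
  # ATPase ORF retained
  fs <- plant_frameshift(ref, "integrase")
  st <- check_orf_integrity(fs, ref)
  expect_identical(unname(st["integrase"]), "frameshift")
  expect_identical(unname(st["atpase"]), "intact")

  # substitution creating an internal TAA: premature stop, verified by an
  # independent brute-force codon scan
  orf1 <- ref$orf_models[1, ]
  codon_pos <- orf1$start + 3 * 50   # 51st codon
  seq_stop <- ISmobilome:::str_replace_range(ref$sequence, codon_pos,
                                             codon_pos + 2, "TAA")
  oracle_codons <- substring(substr(seq_stop, orf1$start, orf1$end),
                             seq(1, orf1$end - orf1$start - 1, 3),
                             seq(3, orf1$end - orf1$start + 1, 3))
  expect_true(any(head(oracle_codons, -1) %in% c("TAA", "TAG", "TGA")))
  st2 <- check_orf_integrity(seq_stop, ref)
  expect_identical(unname(st2["integrase"]), "premature_stop")
  expect_identical(unname(st2["atpase"]), "intact")

  # truncation removing the ATPase ORF entirely
  half <- substr(ref$sequence, 1, orf1$end + 10)
  st3 <- check_orf_integrity(half, ref)
  expect_identical(unname(st3["atpase"]), "absent")
})

test_that("ORF calls agree with the brute-force oracle across random lesions", {
  refs <- test_refs_small()
  ref <- refs$ISS12_A
  orf1 <- ref$orf_models[1, ]
  orf2 <- ref$orf_models[2, ]
  set.seed(90210)
  for (case in 1:60) {
    lesion <- sample(c("none", "del1", "stop", "del3"), 1)
    seq <- ref$sequence
    expected <- c(integrase = "intact", atpase = "intact")
    if (lesion == "del1") {
      pos <- orf1$start + sample(10:(orf1$end - orf1$start - 10), 1)
      seq <- ISmobilome:::str_delete_range(seq, pos, pos)
      expected["integrase"] <- "frameshift"
    } else if (lesion == "stop") {
      codon_i <- sample(5:((orf2$end - orf2$start + 1) / 3 - 5), 1)
      pos <- orf2$start + 3 * (codon_i - 1)
      seq <- ISmobilome:::str_replace_range(seq, pos, pos + 2, "TGA")
      expected["atpase"] <- "premature_stop"
    } else if (lesion == "del3") {
      # in-frame codon deletion: no frameshift; intact unless a stop arises
      codon_i <- sample(5:((orf1$end - orf1$start + 1) / 3 - 5), 1)
      pos <- orf1$start + 3 * (codon_i - 1)
      seq <- ISmobilome:::str_delete_range(seq, pos, pos + 2)
      expected["integrase"] <- "intact"
    }
    st <- check_orf_integrity(seq, ref)
    expect_identical(unname(st["integrase"]), unname(expected["integrase"]),
                     label = paste("integrase lesion", lesion, "case", case))
    expect_identical(unname(st["atpase"]), unname(expected["atpase"]),
                     label = paste("atpase lesion", lesion, "case", case))
  }
})
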