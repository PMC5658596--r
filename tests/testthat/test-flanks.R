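test_that("detect_tsd recovers a constructed directed repeat exactly", {
  # build a locus with the solvent-pump repeat ACCCAGA duplicated around a
  # planted element
  g <- random_dna(3000, seed = 5)
  g <- ISmobilome:::str_replace_range(g, 1500, 1506, "ACCCAGA")
  el <- random_dna(400, seed = 6)
  pl <- plant_insertion(g, 1500, el, "Forward", tsd_len = 7)
  r <- detect_tsd(pl$genome, pl$insertion$start, pl$insertion$end)
  expect_equal(r$dr_len, 7)
  expect_identical(r$dr_seq, "ACCCAGA")
  expect_true(r$flank_ok)
})

test_that("flanks without a shared word give dr_len 0; edge copies are flagged", {
  g <- paste0(strrep("A", 100), strrep("C", 50), strrep("G", 100))
  r <- detect_tsd(g, 101, 150)
  expect_equal(r$dr_len, 0)
  expect_identical(r$dr_seq, "")

  # linear replicon edge: insufficient flank is NA, not 0
  g2 <- random_dna(500, seed = 7)
  r2 <- detect_tsd(g2, 2, 300)
  expect_true(is.na(r2$dr_len))
  expect_false(r2$flank_ok)
})

test_that("detect_tsd equals brute force over every k on random planted cases", {
  set.seed(2024)
  for (case in 1:200) {
    tsd_len <- sample(0:9, 1)
    g <- random_dna(800, gc = runif(1, 0.4, 0.65))
    site <- sample(100:600, 1)
    el <- random_dna(sample(60:150, 1))
    pl <- plant_insertion(g, site, el, sample(c("Forward", "Reverse"), 1),
                          tsd_len)
    ins <- pl$insertion
    r <- detect_tsd(pl$genome, ins$start, ins$end, kmin = 4, kmax = 12)
    # independent exhaustive oracle
    expected <- 0L
    for (k in 4:12) {
      left <- substr(pl$genome, ins$start - k, ins$start - 1)
      right <- substr(pl$genome, ins$end + 1, ins$end + k)
      if (nchar(left) == k && left == right) expected <- k
    }
    expect_equal(r$dr_len, expected, label = paste("case", case))
    if (expected >= 4) {
      # the planted repeat is recovered (possibly extended by coincidence)
      expect_gte(r$dr_len, min(tsd_len, 12))
    }
  }
})

test_that("TSDs are reverse-complement invariant and wrap-aware", {
  refs <- test_refs()
  g <- random_dna(9000, seed = 12)
  pl <- plant_insertion(g, 4500, refs$ISS12_A, "Forward", 8)
  ins <- pl$insertion
  r <- detect_tsd(pl$genome, ins$start, ins$end)
  g_rc <- revcomp(pl$genome)
  len <- nchar(pl$genome)
  r_rc <- detect_tsd(g_rc, len - ins$end + 1, len - ins$start + 1)
  expect_equal(r_rc$dr_len, r$dr_len)
  expect_identical(r_rc$dr_seq, revcomp(r$dr_seq))

  # a copy spanning the origin of a circular replicon
  rot <- ISmobilome:::rotate_seq(pl$genome, ins$start + 1000)
  rlen <- nchar(rot)
  new_start <- rlen - 1000 + 1
  new_end <- ins$end - ins$start + 1 - 1000
  r_wrap <- detect_tsd(rot, new_start, new_end, circular = TRUE, wraps = TRUE)
  expect_equal(r_wrap$dr_len, r$dr_len)
  expect_identical(r_wrap$dr_seq, r$dr_seq)
})

test_that("terminal inverted repeats are found with and without mismatches", {
  # perfect 20 bp IR by construction
  ref <- make_is_reference(33, length = 1200, ir_len = 20)
  irs <- detect_irs(ref$sequence, window = 150, min_len = 15)
  expect_gte(nrow(irs), 1)
  top <- irs[1, ]
  expect_gte(top$length, 20)
  expect_equal(top$mismatches, 0)
  expect_equal(top$left_start, 1)
  expect_equal(top$right_end, 1200)

  # planted single substitution inside the IR, 10% mismatch budget
  damaged <- ISmobilome:::str_replace_range(
    ref$sequence, 10, 10,
    setdiff(c("A", "C", "G", "T"), substr(ref$sequence, 10, 10))[1])
  irs_d <- detect_irs(damaged, window = 60, min_len = 15,
                      max_mismatch_frac = 0.1)
  expect_gte(nrow(irs_d), 1)
  expect_equal(irs_d$mismatches[1], 1)
  expect_gte(irs_d$length[1], 20)

  # a random element of the full size carries no long perfect IR
  for (s in 101:103) {
    rnd <- random_dna(2600, gc = 0.55, seed = s)
    expect_equal(nrow(detect_irs(rnd, window = 150, min_len = 14)), 0)
  }

  expect_error(detect_irs(ref$sequence, window = 900), "window")
})

test_that("flank conservation separates motifs from uniform-random flanks", {
  # identical flanks: raw IC 2 bits everywhere, clear consensus
  fl_same <- rep(random_dna(30, seed = 14), 33)
  fc_same <- flank_conservation(fl_same)
  expect_true(all(abs(fc_same$ic_raw - 2) < 1e-12))
  expect_identical(fc_same$verdict, "consensus")

  # uniform-random flanks, n = 33: no consensus, and the corrected mean IC
  # sits at the analytic small-sample expectation (~0)
  set.seed(15)
  means <- replicate(5, {
    fl <- vapply(1:33, function(i) random_dna(30, gc = 0.5), character(1))
    fc <- flank_conservation(fl)
    expect_identical(fc$verdict, "no consensus")
    mean(fc$ic)
  })
  expect_lt(abs(mean(means)), 0.05)

  # planted 4-mer motif at a fixed offset in otherwise random flanks
  set.seed(16)
  fl_motif <- vapply(1:33, function(i) {
    x <- random_dna(30, gc = 0.5)
    ISmobilome:::str_replace_range(x, 11, 14, "TTAA")
  }, character(1))
  fc_m <- flank_conservation(fl_motif)
  expect_identical(fc_m$verdict, "consensus")
  expect_equal(fc_m$window_start, 11)

  expect_error(flank_conservation(c("ACGT", "ACG", "ACGT", "ACGT", "ACGT")),
               "equal length")
  expect_error(flank_conservation(c("ACGT", "ACGT")), "at least 5")
})
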