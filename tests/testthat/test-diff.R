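trio_case <- function() {
  cached("trio1", make_mobilome_trio(601, length = 30000, n_copies = 6,
                                     n_previous = 2, refs = test_refs()))
}

test_that("probes are the expected strings and the empty-site probe keeps one DR", {
  g <- random_dna(4000, seed = 71)
  el <- random_dna(500, seed = 72)
  pl <- plant_insertion(g, 2000, el, "Forward", tsd_len = 7)
  ins <- pl$insertion
  pr <- build_probes(pl$genome, ins$start, ins$end, 7, probe_flank = 50)

  # string-construction oracle from the ancestral genome
  expect_identical(pr$empty, substr(g, 2000 + 7 - 50, 2000 + 7 + 49))
  expect_identical(pr$left, paste0(substr(pl$genome, ins$start - 50, ins$start - 1),
                                   substr(el, 1, 50)))
  expect_identical(pr$right, paste0(substr(el, 451, 500),
                                    substr(pl$genome, ins$end + 1, ins$end + 50)))
  # the DR occurs exactly once in the empty-site probe at the junction
  tsd <- ins$tsd_seq
  hits <- gregexpr(tsd, pr$empty, fixed = TRUE)[[1]]
  expect_equal(as.integer(hits), 44)  # probe_flank - tsd_len + 1
  expect_true(pr$probe_unique)

  # tsd_len 0: empty-site probe is the plain flank concatenation
  pl0 <- plant_insertion(g, 2000, el, "Forward", tsd_len = 0)
  i0 <- pl0$insertion
  pr0 <- build_probes(pl0$genome, i0$start, i0$end, 0, probe_flank = 50)
  expect_identical(pr0$empty, substr(g, 1950, 2049))

  # a copy inside a tandem duplication cannot have unique probes
  dup_block <- substr(g, 1900, 2300)
  g_dup <- paste0(g, dup_block)
  pl_d <- plant_insertion(g_dup, 2000, el, "Forward", 7)
  pr_d <- build_probes(pl_d$genome, pl_d$insertion$start, pl_d$insertion$end, 7)
  expect_false(pr_d$probe_unique)

  expect_error(build_probes(pl$genome, 10, ins$end, 7), "flank")
})

test_that("reads from mutated vs ancestral genomes give present vs absent", {
  g <- random_dna(20000, seed = 81)
  el <- test_refs()$ISS12_A
  pl <- plant_insertion(g, 9000, el, "Forward", 7)
  ins <- pl$insertion
  pr <- build_probes(pl$genome, ins$start, ins$end, 7)

  reads_mut <- simulate_reads(pl$genome, 150, 20, seed = 82)
  reads_anc <- simulate_reads(g, 150, 20, seed = 83)

  expect_identical(call_presence(pr, reads_mut)$verdict, "present")
  expect_identical(call_presence(pr, reads_anc)$verdict, "absent")

  # contradictory evidence: a 50/50 mixture supports everything
  mixture <- c(reads_mut, reads_anc)
  expect_identical(call_presence(pr, mixture)$verdict, "ambiguous")

  # empty evidence source
  expect_identical(call_presence(pr, list(reads = character(0)))$verdict,
                   "ambiguous")

  # assembly evidence instead of reads
  expect_identical(call_presence(pr, pl$genome)$verdict, "present")
  expect_identical(call_presence(pr, g)$verdict, "absent")
})

test_that("verdicts are invariant under read-order shuffling", {
  g <- random_dna(15000, seed = 91)
  pl <- plant_insertion(g, 7000, test_refs()$ISS12_A, "Reverse", 6)
  ins <- pl$insertion
  pr <- build_probes(pl$genome, ins$start, ins$end, 6)
  reads <- simulate_reads(g, 150, 15, seed = 92)
  v1 <- call_presence(pr, reads)
  set.seed(93)
  v2 <- call_presence(pr, sample(reads))
  expect_identical(v1$verdict, v2$verdict)
  expect_equal(v1$empty_support, v2$empty_support)
})

test_that("trio diff recovers exactly the sites unique to the derived genome", {
  trio <- trio_case()
  truth <- trio$truth
  truth_sorted <- truth[order(truth$start), ]
  ev <- list(
    previous = simulate_reads(trio$previous, 150, 20, seed = 601),
    revertant = simulate_reads(trio$revertant, 150, 20, seed = 602)
  )
  dm <- diff_mobilomes(trio$derived, truth_sorted, ev)
  calls <- dm$calls

  # no ambiguous calls on clean 20x data with unique probes
  expect_true(all(calls$verdict %in% c("present", "absent")))

  prev_verdicts <- calls$verdict[calls$source == "previous"]
  expect_identical(prev_verdicts,
                   ifelse(truth_sorted$in_previous, "present", "absent"))

  # the revertant lacks exactly the excised copy
  rev_truth <- truth_sorted$target_pos != truth$target_pos[trio$revert_index]
  rev_verdicts <- calls$verdict[calls$source == "revertant"]
  expect_identical(rev_verdicts, ifelse(rev_truth, "present", "absent"))

  # unique-to-backbone = sites absent from every source: the revertant
  # still carries every non-reverted copy, so only a reverted site that is
  # also missing from the previous genome can be unique here
  expected_unique <- truth_sorted$target_pos[!truth_sorted$in_previous & !rev_truth]
  got <- dm$matrix$copy_id %in% dm$unique_to_backbone
  expect_identical(truth_sorted$target_pos[got], expected_unique)

  # against the previous genome alone, the unique sites are exactly the
  # planted extras
  dm_prev <- diff_mobilomes(trio$derived, truth_sorted, ev["previous"])
  expect_identical(
    truth_sorted$target_pos[dm_prev$matrix$copy_id %in% dm_prev$unique_to_backbone],
    truth_sorted$target_pos[!truth_sorted$in_previous])
})

test_that("identical genomes share every site", {
  fx <- test_fixture()
  tr <- fx$truth[order(fx$truth$start), ]
  dm <- diff_mobilomes(fx$mutated, tr,
                       list(same = simulate_reads(fx$mutated, 150, 15,
                                                  seed = 71)))
  expect_true(all(dm$calls$verdict == "present"))
  expect_equal(length(dm$unique_to_backbone), 0)
})

test_that("starving coverage degrades calls only toward ambiguous", {
  g <- random_dna(15000, seed = 95)
  pl <- plant_insertion(g, 7000, test_refs()$ISS12_A, "Forward", 7)
  ins <- pl$insertion
  pr <- build_probes(pl$genome, ins$start, ins$end, 7)
  for (cov in c(10, 3, 1, 0.3)) {
    v <- call_presence(pr, simulate_reads(pl$genome, 150, cov, seed = 96))
    expect_true(v$verdict %in% c("present", "ambiguous"),
                label = paste("coverage", cov))
  }
})
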