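#' Cleanly excise an IS copy
#'
#' Removes the element plus exactly one copy of its directed repeat — the
#' clean-excision outcome that restores the pre-insertion sequence (the
#' removal of exactly one DR copy is what makes a revertant's disrupted
#' gene whole again). The right-hand DR copy is the one removed; for exact
#' repeats the choice is immaterial.
#'
#' @param genome DNA string carrying the copy.
#' @param start,end copy coordinates (repeats excluded).
#' @param dr_len directed-repeat length (0 for a repeat-less insertion).
#' @param check verify that both flanks actually carry the same
#'   `dr_len`-mer before cutting (default TRUE).
#' @return the excised genome; length = input − element − dr_len.
#' @export
excise <- function(genome, start, end, dr_len, check = TRUE) {
  len <- nchar(genome)
  stopifnot(start >= 1, end >= start, end + dr_len <= len, dr_len >= 0)
  if (check && dr_len > 0) {
    if (start - dr_len < 1)
      stop("no room for a ", dr_len, " bp repeat left of the copy")
    left <- substr(genome, start - dr_len, start - 1)
    right <- substr(genome, end + 1, end + dr_len)
    if (left != right)
      stop("flanks disagree with the stated ", dr_len,
           " bp directed repeat (", left, " vs ", right, ")")
  }
  str_delete_range(genome, start, end + dr_len)
}

#' Enumerate excision cuts that exactly restore a disrupted gene
#'
#' For a copy inserted inside a gene, evaluates every excision leaving 0, 1
#' or 2 DR copies, plus every off-by-k variation of the cut boundaries for
#' |k| <= `max_shift`, and reports which cut outcomes translate to a
#' protein exactly equal to the ancestral one. For an in-CDS insertion
#' whose DR length is not divisible by 3, only the clean excision (one DR
#' copy retained, exact boundaries) restores the gene; cut choices that
#' preserve the reading frame without restoring the gene (e.g. keeping both
#' copies of a 6-bp repeat) are flagged `frame_preserved` but not restoring.
#'
#' Restoration is asserted at the nucleotide level (`exact_restore`: the
#' gene sequence equals the ancestral gene exactly), matching how revertants
#' are verified by sequencing; protein-level equality is reported separately
#' (`protein_restore`) because a cut shifted into the element can leave a
#' junction scar that is coincidentally synonymous — a protein-identical but
#' sequence-scarred outcome. Cuts shifted into the directed repeat itself
#' reproduce the clean sequence byte-for-byte; restoring excisions are
#' therefore counted over unique outcome sequences.
#'
#' @param genome DNA string carrying the copy.
#' @param start,end copy coordinates.
#' @param dr_len directed-repeat length at the site.
#' @param gene_start,gene_end gene model coordinates in `genome` (the
#'   disrupted gene, insertion included, so gene_end is the ancestral end
#'   plus element and repeat length); the copy must lie within the gene.
#' @param strand gene strand ("+" or "-").
#' @param ref_gene the ancestral (undisrupted) gene nucleotide sequence in
#'   gene orientation, stop codon included.
#' @param max_shift off-by-k range for the cut boundaries (default 3).
#' @return tibble: cut_left, cut_right, removed_len, scar_len (excess bases
#'   left relative to the clean cut), frame_preserved, exact_restore,
#'   protein_restore, outcome_key; attribute `n_restoring_outcomes` counts
#'   unique sequence-restoring outcomes.
#' @export
enumerate_restoring_excisions <- function(genome, start, end, dr_len,
                                          gene_start, gene_end, strand = "+",
                                          ref_gene, max_shift = 3) {
  len <- nchar(genome)
  if (gene_start > start || gene_end < end)
    stop("the copy does not lie within the supplied gene model")
  elem_len <- end - start + 1L
  base_cuts <- rbind(
    c(start, end),                       # keep both DR copies
    c(start, end + dr_len),              # clean: keep one copy
    c(start - dr_len, end + dr_len)      # keep no copy
  )
  shifts <- expand.grid(dl = -max_shift:max_shift, dr = -max_shift:max_shift)
  cuts <- unique(do.call(rbind, lapply(seq_len(nrow(base_cuts)), function(i) {
    cbind(base_cuts[i, 1] + shifts$dl, base_cuts[i, 2] + shifts$dr)
  })))
  cuts <- cuts[cuts[, 1] >= gene_start & cuts[, 2] <= gene_end &
                 cuts[, 1] <= cuts[, 2], , drop = FALSE]
  clean_removed <- elem_len + dr_len
  ref_protein <- translate_to_stop(ref_gene)
  rows <- vector("list", nrow(cuts))
  for (i in seq_len(nrow(cuts))) {
    L <- cuts[i, 1]; R <- cuts[i, 2]
    g2 <- str_delete_range(genome, L, R)
    removed <- R - L + 1L
    scar <- clean_removed - removed
    gene_len2 <- (gene_end - gene_start + 1L) - removed
    gene_seq <- substr(g2, gene_start, gene_start + gene_len2 - 1L)
    if (strand == "-") gene_seq <- revcomp(gene_seq)
    prot <- translate_to_stop(gene_seq)
    # outcome identity: same result length + same local sequence around the
    # ancestral junction (cut-coordinate independent, so equivalent cuts
    # that leave a byte-identical genome collapse to one outcome)
    key <- paste0(nchar(g2), ":",
                  substr(g2, max(1L, start - dr_len - 30L),
                         min(nchar(g2), start + 30L)))
    rows[[i]] <- tibble::tibble(
      cut_left = L, cut_right = R, removed_len = removed, scar_len = scar,
      frame_preserved = scar %% 3 == 0,
      exact_restore = identical(gene_seq, ref_gene),
      protein_restore = identical(prot, ref_protein),
      outcome_key = key
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "n_restoring_outcomes") <-
    length(unique(out$outcome_key[out$exact_restore]))
  out
}

# Translate from the first codon to the first stop (stop excluded).
translate_to_stop <- function(x) {
  aa <- translate_orf(x)
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) substr(aa, 1, stop_at - 1) else aa
}

#' Translate a gene interval of a genome
#'
#' @param genome DNA string.
#' @param gene_start,gene_end gene coordinates.
#' @param strand "+" or "-".
#' @param to_stop translate only up to the first stop codon (default TRUE).
#' @return amino-acid string.
#' @export
translate_gene <- function(genome, gene_start, gene_end, strand = "+",
                           to_stop = TRUE) {
  s <- substr(genome, gene_start, gene_end)
  if (strand == "-") s <- revcomp(s)
  if (to_stop) translate_to_stop(s) else translate_orf(s)
}

#' Verify whether a revertant genome carries a clean excision
#'
#' Locates the insertion site in the revertant via the 5' flank of the
#' original copy and compares the local sequence (site +/- `flank` bp)
#' against three constructed hypotheses: the cleanly excised original
#' (`clean_excision`), the unmodified original (`unchanged`), and an
#' excision retaining both DR copies (`imperfect_excision`). Anything else
#' is `other`.
#'
#' @param original genome string carrying the copy.
#' @param revertant genome string to test.
#' @param start,end,dr_len the copy's coordinates and repeat length in
#'   `original`.
#' @param flank comparison window on each side of the site (default 500).
#' @return one of "clean_excision", "unchanged", "imperfect_excision",
#'   "other".
#' @export
verify_revertant <- function(original, revertant, start, end, dr_len,
                             flank = 500) {
  if (nchar(revertant) == 0) stop("revertant replicon is missing/empty")
  anchor_start <- max(1, start - dr_len - flank)
  anchor <- substr(original, anchor_start, start - dr_len - 1)
  if (nchar(anchor) < 30) stop("insufficient 5' flank to anchor the site")
  hits <- Biostrings::matchPattern(anchor, Biostrings::DNAString(revertant))
  if (length(hits) != 1) return("other")
  after <- hits@ranges@start[1] + nchar(anchor)
  cmp_len <- flank + dr_len + 50L
  seen <- substr(revertant, after, after + cmp_len - 1L)
  hypotheses <- list(
    clean_excision = excise(original, start, end, dr_len, check = FALSE),
    unchanged = original,
    imperfect_excision = str_delete_range(original, start, end)
  )
  for (h in names(hypotheses)) {
    expect <- substr(hypotheses[[h]], start - dr_len, start - dr_len + cmp_len - 1L)
    n <- min(nchar(seen), nchar(expect))
    if (n >= dr_len + 20 && substr(expect, 1, n) == substr(seen, 1, n)) {
      return(h)
    }
  }
  "other"
}
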