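#' Construct a synthetic IS21-family reference element
#'
#' Builds a reference insertion-sequence element with the anatomy of an
#' IS21-family element such as ISS12: two open reading frames (an integrase
#' and an ATPase AAA helper) framed by terminal windows of `terminal_window`
#' bp whose outermost `ir_len` bp form a perfect terminal inverted repeat
#' (the first `ir_len` bases are the reverse complement of the last
#' `ir_len` bases). Both ORFs begin with ATG, end with a stop codon and
#' contain no internal stop codon.
#'
#' @param seed integer seed; the same seed always yields the same element.
#' @param length element length in bp (default 2596, the length of ISS12).
#' @param ir_len length of the terminal inverted repeat, must be at most
#'   `terminal_window`.
#' @param terminal_window length of each ORF-free terminal region (default
#'   150 bp).
#' @param orf_layout optional list with integer entries `orf1_len` and
#'   `orf2_len` (codon-multiple bp, stop codon included) and `gap` between
#'   the ORFs. By default the space between the terminal windows is split
#'   roughly 60/40 between the two ORFs.
#' @param gc GC fraction of the unconstrained backbone positions.
#' @param id element identifier.
#' @return an object of class `is_reference`: a list with `id`, `sequence`,
#'   `orf_models` (tibble: start, end, strand, role), `terminal_window`,
#'   `ir_len`.
#' @export
make_is_reference <- function(seed, length = 2596, ir_len = 20,
                              terminal_window = 150, orf_layout = NULL,
                              gc = 0.58, id = "ISS12_A") {
  stopifnot(length >= 600, ir_len >= 4, ir_len <= terminal_window,
            2 * terminal_window < length)
  avail <- length - 2 * terminal_window
  if (is.null(orf_layout)) {
    orf1_len <- (floor(avail * 0.55) %/% 3) * 3
    gap <- 21
    orf2_len <- ((avail - orf1_len - gap) %/% 3) * 3
    orf_layout <- list(orf1_len = orf1_len, orf2_len = orf2_len, gap = gap)
  }
  orf1_len <- orf_layout$orf1_len
  orf2_len <- orf_layout$orf2_len
  gap <- orf_layout$gap
  if (orf1_len < 9 || orf2_len < 9 || orf1_len %% 3 != 0 || orf2_len %% 3 != 0)
    stop("ORF lengths must be codon multiples of at least 9 bp")
  if (orf1_len + orf2_len + gap > avail)
    stop("infeasible ORF layout: ORFs exceed the space between terminal windows")

  with_seed(seed, {
    seq <- random_dna(length, gc = gc)
    orf1_start <- terminal_window + 1
    orf1_end <- orf1_start + orf1_len - 1
    orf2_start <- orf1_end + gap + 1
    orf2_end <- orf2_start + orf2_len - 1
    orf1 <- paste0("ATG", sample_nonstop_codons(orf1_len / 3 - 2, gc), "TAA")
    orf2 <- paste0("ATG", sample_nonstop_codons(orf2_len / 3 - 2, gc), "TAA")
    seq <- str_replace_range(seq, orf1_start, orf1_end, orf1)
    seq <- str_replace_range(seq, orf2_start, orf2_end, orf2)
    # terminal inverted repeat: right terminus mirrors the left
    left_ir <- substr(seq, 1, ir_len)
    seq <- str_replace_range(seq, length - ir_len + 1, length, revcomp(left_ir))
    structure(
      list(
        id = id,
        sequence = seq,
        orf_models = tibble::tibble(
          start = c(orf1_start, orf2_start),
          end = c(orf1_end, orf2_end),
          strand = c("+", "+"),
          role = c("integrase", "atpase")
        ),
        terminal_window = terminal_window,
        ir_len = ir_len
      ),
      class = "is_reference"
    )
  })
}

#' @export
print.is_reference <- function(x, ...) {
  cat(sprintf("<is_reference> %s: %d bp, %d ORFs, terminal window %d bp\n",
              x$id, nchar(x$sequence), nrow(x$orf_models), x$terminal_window))
  invisible(x)
}

# Accept either an is_reference or a bare DNA string.
ref_sequence <- function(ref) {
  if (inherits(ref, "is_reference")) ref$sequence else ref
}

#' Derive a sequence variant at a target nucleotide identity
#'
#' Applies random substitutions (no indels) to a reference element so that
#' the position-wise identity of the result against the input equals the
#' target identity to within rounding (each substituted position is changed
#' to a different base, so the realized mismatch count is exact). This is
#' how diverged element variants — e.g. an 84%-identity ISS12_C-like or a
#' 76%-identity ISS12_D-like copy — are emulated.
#'
#' @param ref an `is_reference` or a DNA string.
#' @param identity target identity in \[0.5, 1\].
#' @param seed optional integer seed.
#' @return a DNA string of the same length as the input.
#' @export
mutate_to_identity <- function(ref, identity, seed = NULL) {
  if (!is.numeric(identity) || identity < 0.5 || identity > 1)
    stop("identity must lie in [0.5, 1]")
  s <- ref_sequence(ref)
  n <- nchar(s)
  n_sub <- round((1 - identity) * n)
  if (n_sub == 0) return(s)
  with_seed(seed, {
    pos <- sample.int(n, n_sub)
    bases <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in pos) bases[p] <- sample(setdiff(DNA_BASES, bases[p]), 1)
    paste(bases, collapse = "")
  })
}

#' Plant a 1-bp deletion inside a reference ORF
#'
#' Utility for emulating a frameshifted variant (the ISS12_D pattern: a
#' frameshift in the integrase ORF with the ATPase ORF retained). The
#' deletion is placed mid-ORF so that downstream codons shift frame.
#'
#' @param ref an `is_reference`.
#' @param orf_role which ORF to damage ("integrase" or "atpase").
#' @param offset 1-based offset of the deleted base within the ORF
#'   (default: the middle of the ORF, snapped off the codon boundary).
#' @return a DNA string one base shorter than the reference.
#' @export
plant_frameshift <- function(ref, orf_role = "integrase", offset = NULL) {
  stopifnot(inherits(ref, "is_reference"))
  orf <- ref$orf_models[ref$orf_models$role == orf_role, ]
  if (nrow(orf) != 1) stop("no unique ORF with role ", orf_role)
  if (is.null(offset)) offset <- ((orf$end - orf$start + 1) %/% 2) + 1
  pos <- orf$start + offset - 1
  if (pos < orf$start + 3 || pos > orf$end - 3)
    stop("deletion offset outside the ORF interior")
  str_delete_range(ref$sequence, pos, pos)
}
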