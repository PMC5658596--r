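#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @importFrom tibble tibble
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character scalar or vector of DNA sequences (ACGTN alphabet).
#' @return character of the same length with each element reverse-complemented.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(reverseComplement(DNAStringSet(x)))
}

#' Sample a random DNA sequence with a target GC content
#'
#' Bases are drawn independently with P(G) = P(C) = gc/2. The realized GC
#' fraction of a multi-kilobase draw is within a fraction of a percentage
#' point of the target.
#'
#' @param n sequence length in bp.
#' @param gc target GC fraction in (0, 1). Default 0.618, the GC content of
#'   the *P. putida* S12 chromosome (the megaplasmid is 0.578).
#' @param seed optional integer seed; when given the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return a character scalar of length `n`.
#' @export
random_dna <- function(n, gc = 0.618, seed = NULL) {
  stopifnot(n >= 0, gc > 0, gc < 1)
  with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
  })
}

# Evaluate `expr` under a fixed seed without clobbering the caller's RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' GC fraction of a DNA string
#' @param x character scalar.
#' @return numeric fraction of G+C bases.
#' @export
gc_content <- function(x) {
  b <- charToRaw(x)
  mean(b == charToRaw("G") | b == charToRaw("C"))
}

# Wrap-aware 1-based inclusive substring. For circular sequences positions
# outside [1, len] are taken modulo the length; for linear sequences an
# out-of-range request returns NA.
wrap_substr <- function(x, i, j, circular = FALSE) {
  len <- nchar(x)
  if (!circular) {
    if (i < 1 || j > len || j < i) return(NA_character_)
    return(substr(x, i, j))
  }
  if (j - i + 1 > len) stop("requested span longer than the circular sequence")
  i0 <- ((i - 1) %% len) + 1
  j0 <- ((j - 1) %% len) + 1
  if (i0 <= j0) substr(x, i0, j0) else paste0(substr(x, i0, len), substr(x, 1, j0))
}

# Rotate a circular sequence so that position `new_origin` becomes base 1.
rotate_seq <- function(x, new_origin) {
  len <- nchar(x)
  o <- ((new_origin - 1) %% len) + 1
  if (o == 1) return(x)
  paste0(substr(x, o, len), substr(x, 1, o - 1))
}

# Hamming mismatch positions between two equal-length strings (raw compare,
# fast for megabase strings).
hamming_mismatches <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  which(charToRaw(a) != charToRaw(b))
}

# Fraction of identical positions between two equal-length strings.
hamming_identity <- function(a, b) {
  n <- nchar(a)
  if (n == 0L) return(NA_real_)
  1 - length(hamming_mismatches(a, b)) / n
}

# Translate an in-frame DNA string to amino acids; "*" marks stops.
# Trailing partial codons are dropped.
translate_orf <- function(x) {
  n <- nchar(x) - nchar(x) %% 3
  if (n < 3) return("")
  codons <- substring(x, seq(1, n - 2, by = 3), seq(3, n, by = 3))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Sample `n` non-stop codons, weighted so coding regions hit a target GC.
sample_nonstop_codons <- function(n, gc = 0.5) {
  pool <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- vapply(strsplit(pool, ""), function(b) prod(base_p[b]), numeric(1))
  paste(sample(pool, n, replace = TRUE, prob = w), collapse = "")
}

# Replace the [start, end] slice of a string.
str_replace_range <- function(x, start, end, value) {
  stopifnot(nchar(value) == end - start + 1)
  paste0(substr(x, 1, start - 1), value, substr(x, end + 1, nchar(x)))
}

# Remove the [start, end] slice of a string.
str_delete_range <- function(x, start, end) {
  paste0(substr(x, 1, start - 1), substr(x, end + 1, nchar(x)))
}
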