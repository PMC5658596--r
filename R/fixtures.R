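#' Plant one IS element into a genome
#'
#' Inserts an element at a target site with a target-site duplication (TSD):
#' the `tsd_len` ancestral bases starting at `site` are duplicated so that
#' after insertion one copy flanks each end of the element (the directed
#' repeat of IS anatomy). The element itself excludes the repeats. Reverse
#' orientation inserts the reverse complement of the element.
#'
#' @param genome ancestral DNA string.
#' @param site 1-based position of the first duplicated base in the
#'   ancestral genome (the insertion point).
#' @param element an `is_reference` or DNA string to insert.
#' @param orientation "Forward" or "Reverse".
#' @param tsd_len length of the target-site duplication, 0 to 12. The
#'   IS21-family elements emulated here produce 5 to 8 bp duplications with
#'   7 bp dominant.
#' @param truncation optional list(keep = fraction in (0,1), end = "left" or
#'   "right") to plant a partial copy: "left" keeps the 5' portion of the
#'   element, "right" the 3' portion (before orientation is applied).
#' @param is_id identifier recorded in the returned truth row.
#' @param existing optional truth tibble of previously planted copies (in
#'   the coordinates of `genome`); planting inside one of them is an error.
#' @return list with `genome` (mutated string) and `insertion` (one-row
#'   tibble: is_id, target_pos, tsd_len, tsd_seq, orientation, elem_len,
#'   start, end — copy coordinates in the mutated genome, 1-based inclusive,
#'   repeats excluded).
#' @export
plant_insertion <- function(genome, site, element, orientation = "Forward",
                            tsd_len = 7, truncation = NULL, is_id = "IS",
                            existing = NULL) {
  len <- nchar(genome)
  stopifnot(site >= 1, site <= len, tsd_len >= 0, tsd_len <= 12,
            orientation %in% c("Forward", "Reverse"))
  if (site + tsd_len - 1 > len)
    stop("target site too close to the sequence end for a ", tsd_len, " bp TSD")
  if (!is.null(existing) && nrow(existing) > 0) {
    inside <- site >= (existing$start - existing$tsd_len) & site <= existing$end
    if (any(inside))
      stop("target site ", site, " lies inside a previously planted element")
  }
  el <- ref_sequence(element)
  if (!is.null(truncation)) {
    stopifnot(truncation$keep > 0, truncation$keep < 1,
              truncation$end %in% c("left", "right"))
    keep_n <- max(1L, round(truncation$keep * nchar(el)))
    el <- if (truncation$end == "left") substr(el, 1, keep_n)
          else substr(el, nchar(el) - keep_n + 1, nchar(el))
  }
  if (orientation == "Reverse") el <- revcomp(el)
  tsd_seq <- if (tsd_len > 0) substr(genome, site, site + tsd_len - 1) else ""
  mutated <- paste0(
    substr(genome, 1, site + tsd_len - 1), # left flank incl. first TSD copy
    el,
    substr(genome, site, len)              # second TSD copy + right flank
  )
  start <- site + tsd_len
  tibble_row <- tibble::tibble(
    is_id = is_id, target_pos = site, tsd_len = tsd_len, tsd_seq = tsd_seq,
    orientation = orientation, elem_len = nchar(el),
    start = start, end = start + nchar(el) - 1
  )
  list(genome = mutated, insertion = tibble_row)
}

#' Plant a batch of insertions given in ancestral coordinates
#'
#' Sites are interpreted in the coordinates of the ancestral genome; the
#' returned truth table carries copy coordinates in the final mutated
#' genome. Sites closer than `tsd_len` + 1 bp apart are rejected.
#'
#' @param genome ancestral DNA string.
#' @param sites tibble with columns target_pos, element (list column or
#'   character), orientation, tsd_len, is_id, and optionally truncation
#'   (list column).
#' @return list(genome, truth) where truth has one row per insertion, sorted
#'   by target_pos.
#' @export
plant_insertions <- function(genome, sites) {
  stopifnot(nrow(sites) > 0)
  sites <- sites[order(sites$target_pos), ]
  if (any(diff(sites$target_pos) <= sites$tsd_len[-nrow(sites)]))
    stop("insertion sites overlap their TSD footprints")
  g <- genome
  rows <- vector("list", nrow(sites))
  # plant right-to-left so earlier sites keep ancestral coordinates
  for (i in rev(seq_len(nrow(sites)))) {
    s <- sites[i, ]
    el <- if (is.list(sites$element)) s$element[[1]] else s$element
    trunc <- if ("truncation" %in% names(sites)) s$truncation[[1]] else NULL
    res <- plant_insertion(g, s$target_pos, el, s$orientation, s$tsd_len,
                           truncation = trunc, is_id = s$is_id)
    g <- res$genome
    rows[[i]] <- res$insertion
  }
  truth <- do.call(rbind, rows)
  # shift copy coordinates for the insertions planted downstream of each site
  shift <- cumsum(c(0L, truth$elem_len + truth$tsd_len))[seq_len(nrow(truth))]
  truth$start <- as.integer(truth$target_pos + truth$tsd_len + shift)
  truth$end <- as.integer(truth$start + truth$elem_len - 1)
  list(genome = g, truth = truth)
}

# Default TSD length distribution: the observed directed-repeat length
# census over 33 insertion sites (24 of length 7, 4 of 6, 4 of 8, 1 of 5).
TSD_LENGTH_WEIGHTS <- c("5" = 1, "6" = 4, "7" = 24, "8" = 4)

# Default variant copy-number weights: 28 primary-variant copies, 4 of an
# 84%-identity variant, 1 frameshifted 76%-identity variant.
VARIANT_WEIGHTS <- c(ISS12_A = 28, ISS12_C = 4, ISS12_D = 1)

#' Build the standard synthetic reference set
#'
#' One primary reference element plus two diverged variants derived from it:
#' a C-like variant at 84% nucleotide identity with both ORFs' reading
#' frames intact in their projection, and a D-like variant at 76% identity
#' carrying an explicit 1-bp deletion (frameshift) in the integrase ORF.
#'
#' @param seed integer seed.
#' @param length primary element length (default 2596 bp).
#' @return named list of `is_reference` objects (the variants share the
#'   primary's ORF model coordinates; the D variant is one base shorter).
#' @export
make_reference_set <- function(seed, length = 2596) {
  primary <- make_is_reference(seed, length = length, id = "ISS12_A")
  var_c <- primary
  var_c$id <- "ISS12_C"
  var_c$sequence <- mutate_to_identity(primary, 0.84, seed = seed + 1L)
  var_d <- primary
  var_d$id <- "ISS12_D"
  var_d$sequence <- plant_frameshift(primary, "integrase")
  var_d$sequence <- mutate_to_identity(var_d$sequence, 0.77, seed = seed + 2L)
  list(ISS12_A = primary, ISS12_C = var_c, ISS12_D = var_d)
}

#' Generate a synthetic replicon with planted IS insertions
#'
#' Emulates a bacterial replicon of configurable GC content carrying a
#' configurable number of IS copies with known ground truth: variant mix,
#' orientations, TSD lengths drawn from the observed directed-repeat length
#' distribution, and optional truncated copies. The replicon is tiled with
#' CDS features (real ORFs: ATG start, stop codon, no internal stops) so
#' insertion contexts and gene-restoration checks can be evaluated.
#'
#' @param seed integer seed; fixtures are bit-reproducible from it.
#' @param length replicon length in bp.
#' @param gc GC fraction (0.618 chromosome-like, 0.578 plasmid-like).
#' @param circular logical.
#' @param n_copies number of planted copies.
#' @param refs named list of `is_reference` (default `make_reference_set`).
#' @param variants per-copy variant ids (recycled/sampled from
#'   `VARIANT_WEIGHTS` when NULL).
#' @param tsd_lens per-copy TSD lengths (sampled from
#'   `TSD_LENGTH_WEIGHTS` when NULL).
#' @param orientations per-copy orientations (sampled when NULL).
#' @param gene_len,intergenic CDS tile length (codon multiple) and gap.
#' @param min_gap minimum distance between insertion points.
#' @param name replicon name recorded in the truth table.
#' @return object of class `genome_fixture`: list(name, ancestral, mutated,
#'   circular, gc, annotations, truth, refs, seed).
#' @export
make_genome_fixture <- function(seed, length = 50000, gc = 0.618,
                                circular = TRUE, n_copies = 10, refs = NULL,
                                variants = NULL, tsd_lens = NULL,
                                orientations = NULL, gene_len = 900,
                                intergenic = 150, min_gap = 400,
                                name = "chromosome") {
  stopifnot(length >= 10000, n_copies >= 0)
  if (is.null(refs)) refs <- make_reference_set(seed + 1000L)
  with_seed(seed, {
    ancestral <- random_dna(length, gc = gc)
    ann <- tile_cds_annotation(length, gene_len = gene_len,
                               intergenic = intergenic)
    # overwrite each CDS with a translatable ORF so gene models are real
    for (i in seq_len(nrow(ann))) {
      orf <- paste0("ATG", sample_nonstop_codons(gene_len / 3 - 2, gc), "TAA")
      if (ann$strand[i] == "-") orf <- revcomp(orf)
      ancestral <- str_replace_range(ancestral, ann$start[i], ann$end[i], orf)
    }
    truth <- NULL
    mutated <- ancestral
    if (n_copies > 0) {
      if (is.null(variants))
        variants <- sample(names(VARIANT_WEIGHTS), n_copies, replace = TRUE,
                           prob = VARIANT_WEIGHTS / sum(VARIANT_WEIGHTS))
      if (is.null(tsd_lens))
        tsd_lens <- as.integer(sample(names(TSD_LENGTH_WEIGHTS), n_copies,
                                      replace = TRUE,
                                      prob = TSD_LENGTH_WEIGHTS / sum(TSD_LENGTH_WEIGHTS)))
      if (is.null(orientations))
        orientations <- sample(c("Forward", "Reverse"), n_copies, replace = TRUE)
      sites <- sample_spaced_sites(n_copies, lo = 500, hi = length - 500,
                                   min_gap = min_gap)
      site_tbl <- tibble::tibble(
        target_pos = sites,
        element = lapply(variants, function(v) refs[[v]]$sequence),
        orientation = orientations,
        tsd_len = tsd_lens,
        is_id = variants
      )
      planted <- plant_insertions(ancestral, site_tbl)
      mutated <- planted$genome
      truth <- planted$truth
      truth$replicon <- name
      primary <- refs[[1]]$sequence
      truth$identity <- vapply(truth$is_id, function(v) {
        s <- refs[[v]]$sequence
        if (nchar(s) == nchar(primary)) hamming_identity(s, primary) else NA_real_
      }, numeric(1))
      truth <- truth[, c("replicon", "is_id", "target_pos", "tsd_len",
                         "tsd_seq", "orientation", "elem_len", "start",
                         "end", "identity")]
    }
    structure(
      list(name = name, ancestral = ancestral, mutated = mutated,
           circular = circular, gc = gc, annotations = ann, truth = truth,
           refs = refs, seed = seed),
      class = "genome_fixture"
    )
  })
}

#' @export
print.genome_fixture <- function(x, ...) {
  cat(sprintf(
    "<genome_fixture> %s: %d bp ancestral, %d planted copies, %s, GC %.3f\n",
    x$name, nchar(x$ancestral),
    if (is.null(x$truth)) 0L else nrow(x$truth),
    if (x$circular) "circular" else "linear", gc_content(x$ancestral)))
  invisible(x)
}

# Tile a replicon with CDS features separated by intergenic gaps.
tile_cds_annotation <- function(length, gene_len = 900, intergenic = 150) {
  starts <- seq(intergenic + 1, length - gene_len - intergenic,
                by = gene_len + intergenic)
  n <- length(starts)
  tibble::tibble(
    feature_id = sprintf("gene_%04d", seq_len(n)),
    start = starts,
    end = starts + gene_len - 1,
    strand = sample(c("+", "-"), n, replace = TRUE),
    type = "CDS",
    product = sprintf("hypothetical protein %04d", seq_len(n))
  )
}

# Rejection-sample n positions in [lo, hi] pairwise at least min_gap apart.
sample_spaced_sites <- function(n, lo, hi, min_gap) {
  if (n == 0) return(integer(0))
  for (attempt in 1:200) {
    s <- sort(sample(lo:hi, n))
    if (n == 1 || all(diff(s) >= min_gap)) return(s)
  }
  stop("could not place ", n, " sites with min_gap ", min_gap,
       " in [", lo, ", ", hi, "]")
}

#' Build an ancestral / derived / revertant genome trio
#'
#' Emulates the comparative setting of a re-sequenced strain: a `previous`
#' genome carrying only the subset of insertions marked present in earlier
#' sequence data, a `derived` genome carrying all of them, and a
#' `revertant` derived genome from which one designated copy (by default
#' the last planted one) has been cleanly excised.
#'
#' @param seed integer seed.
#' @param n_copies total planted copies in the derived genome.
#' @param n_previous how many of them are also in the previous genome.
#' @param revert_index which copy (row of truth, by target position order)
#'   is excised in the revertant.
#' @inheritParams make_genome_fixture
#' @return list(fixture, previous, derived, revertant, truth) where truth
#'   gains a logical column `in_previous`; `previous` coordinates refer to
#'   that genome's own truth table (attribute "truth").
#' @export
make_mobilome_trio <- function(seed, length = 40000, gc = 0.618,
                               circular = FALSE, n_copies = 8,
                               n_previous = 3, revert_index = NULL,
                               refs = NULL) {
  fx <- make_genome_fixture(seed, length = length, gc = gc,
                            circular = circular, n_copies = n_copies,
                            refs = refs)
  truth <- fx$truth
  with_seed(seed + 1L, {
    prev_idx <- sort(sample(seq_len(n_copies), n_previous))
  })
  truth$in_previous <- seq_len(n_copies) %in% prev_idx
  sites_prev <- tibble::tibble(
    target_pos = truth$target_pos[prev_idx],
    element = lapply(truth$is_id[prev_idx], function(v) fx$refs[[v]]$sequence),
    orientation = truth$orientation[prev_idx],
    tsd_len = truth$tsd_len[prev_idx],
    is_id = truth$is_id[prev_idx]
  )
  previous <- plant_insertions(fx$ancestral, sites_prev)
  if (is.null(revert_index)) revert_index <- n_copies
  rv <- truth[revert_index, ]
  revertant <- excise(fx$mutated, rv$start, rv$end, rv$tsd_len)
  fx$truth <- truth
  list(fixture = fx, previous = structure(previous$genome, truth = previous$truth),
       derived = fx$mutated, revertant = revertant, truth = truth,
       revert_index = revert_index)
}

#' Simulate error-free shotgun reads
#'
#' Uniform sampling of exact substrings from both strands; circular
#' replicons are sampled across the origin. Used to emulate the re-assembly
#' evidence behind presence/absence calling — no sequencing-error model.
#'
#' @param genome DNA string.
#' @param read_len read length in bp (must be shorter than the genome).
#' @param coverage target fold coverage; the read count is
#'   round(coverage * genome_len / read_len).
#' @param seed optional integer seed.
#' @param circular logical.
#' @return character vector of reads (forward- or reverse-strand).
#' @export
simulate_reads <- function(genome, read_len = 150, coverage = 20,
                           seed = NULL, circular = FALSE) {
  len <- nchar(genome)
  if (read_len >= len) stop("read_len must be shorter than the genome")
  stopifnot(coverage > 0)
  n <- round(coverage * len / read_len)
  with_seed(seed, {
    if (circular) {
      starts <- sample.int(len, n, replace = TRUE)
      gx <- paste0(genome, substr(genome, 1, read_len - 1))
    } else {
      starts <- sample.int(len - read_len + 1, n, replace = TRUE)
      gx <- genome
    }
    reads <- substring(gx, starts, starts + read_len - 1)
    rev <- sample(c(TRUE, FALSE), n, replace = TRUE)
    reads[rev] <- revcomp(reads[rev])
    reads
  })
}

#' Load a transcribed insertion-site table
#'
#' Reads the 8-column TSV layout used for the in-package insertion-site
#' survey fixture: replicon, variant, position ("start-end", which may wrap
#' the origin of a circular replicon, i.e. end < start), orientation,
#' presence_in_previous (Yes/No), dr_seq, dr_len, context (free text with a
#' trailing "[a]", "[b]" or "[c]" code: in-gene, intergenic, promoter).
#' Records violating dr_len == nchar(dr_seq) or carrying an unknown context
#' code are load errors, not silently kept.
#'
#' @param path TSV file path. The packaged survey table is at
#'   `system.file("extdata", "pputida_S12A_insertion_sites.tsv",
#'   package = "ISmobilome")`.
#' @return tibble of class `insertion_record` with columns replicon,
#'   variant, start, end, wraps, orientation, presence_in_previous, dr_seq,
#'   dr_len, context_code, context_text.
#' @export
load_insertion_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2)
    stop("insertion table has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) != 8)
    stop("expected 8 tab-separated columns, found ", length(header))
  rows <- fields[-1]
  parse_row <- function(f, rownum) {
    if (length(f) != 8)
      stop("row ", rownum, ": expected 8 columns, found ", length(f))
    pos <- strsplit(f[3], "-", fixed = TRUE)[[1]]
    if (length(pos) != 2 || anyNA(suppressWarnings(as.integer(pos))))
      stop("row ", rownum, ": malformed position '", f[3], "'")
    if (!f[4] %in% c("Forward", "Reverse"))
      stop("row ", rownum, ": unknown orientation '", f[4], "'")
    if (!f[5] %in% c("Yes", "No"))
      stop("row ", rownum, ": unknown presence flag '", f[5], "'")
    dr_len <- suppressWarnings(as.integer(f[7]))
    if (is.na(dr_len) || dr_len != nchar(f[6]))
      stop("row ", rownum, ": directed-repeat length ", f[7],
           " does not match sequence '", f[6], "'")
    m <- regmatches(f[8], regexec("^(.*) \\[([a-z])\\]$", f[8]))[[1]]
    if (length(m) != 3 || !m[3] %in% c("a", "b", "c"))
      stop("row ", rownum, ": unknown or missing context code in '", f[8], "'")
    start <- as.integer(pos[1]); end <- as.integer(pos[2])
    tibble::tibble(
      replicon = f[1], variant = f[2], start = start, end = end,
      wraps = end < start, orientation = f[4], presence_in_previous = f[5],
      dr_seq = f[6], dr_len = dr_len, context_code = m[3],
      context_text = m[2]
    )
  }
  out <- do.call(rbind, Map(parse_row, rows, seq_along(rows) + 1L))
  class(out) <- c("insertion_record", class(out))
  out
}
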