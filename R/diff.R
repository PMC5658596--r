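#' Build junction and empty-site probes for one insertion site
#'
#' Three probes diagnose the state of an insertion site in independent
#' evidence (a second assembly or a read set):
#' \describe{
#'   \item{left junction}{`probe_flank` genomic bases immediately 5' of the
#'     copy (ending with the left DR copy) + the first `probe_flank`
#'     element bases;}
#'   \item{right junction}{the mirror at the 3' end;}
#'   \item{empty site}{left flank and right flank joined with exactly one
#'     DR copy retained — the pre-insertion (or cleanly excised) locus.}
#' }
#' Probe uniqueness is checked against the backbone with all element
#' interiors masked (multi-copy elements would otherwise multi-map): each
#' genomic flank must occur exactly once on either strand of the masked
#' backbone.
#'
#' @param genome backbone replicon DNA string (the genome carrying the copy).
#' @param start,end copy coordinates (repeats excluded).
#' @param tsd_len directed-repeat length at this site.
#' @param probe_flank bases taken from each side (default 30: a 60-bp probe
#'   keeps read support comfortably above `min_support` at 20x coverage
#'   with 150-bp reads while staying effectively unique in a bacterial
#'   replicon).
#' @param all_copies optional `is_copies`/truth tibble of every element span
#'   in the backbone, used for interior masking; defaults to just this copy.
#' @param circular logical.
#' @return list(left, right, empty, probe_unique, flank_counts).
#' @export
build_probes <- function(genome, start, end, tsd_len, probe_flank = 30,
                         all_copies = NULL, circular = FALSE) {
  len <- nchar(genome)
  if (!circular && (start - probe_flank < 1 || end + tsd_len + probe_flank > len))
    stop("flank shorter than probe_flank at this site")
  left_flank <- wrap_substr(genome, start - probe_flank, start - 1, circular)
  right_flank <- wrap_substr(genome, end + 1, end + probe_flank, circular)
  elem_head <- wrap_substr(genome, start, start + probe_flank - 1, circular)
  elem_tail <- wrap_substr(genome, end - probe_flank + 1, end, circular)
  # the right flank starts with the second DR copy; the empty-site locus
  # keeps exactly one copy, so skip it on the right
  right_after_dr <- wrap_substr(genome, end + tsd_len + 1,
                                end + tsd_len + probe_flank, circular)
  probes <- list(
    left = paste0(left_flank, elem_head),
    right = paste0(elem_tail, right_flank),
    empty = paste0(left_flank, right_after_dr)
  )
  masked <- genome
  spans <- if (is.null(all_copies)) {
    tibble::tibble(start = start, end = end)
  } else all_copies
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]
    if (e >= s) {
      masked <- str_replace_range(masked, s, e, strrep("N", e - s + 1))
    }
  }
  counts <- c(
    left_flank = count_occurrences(masked, left_flank),
    right_flank = count_occurrences(masked, right_after_dr)
  )
  probes$probe_unique <- all(counts == 1)
  probes$flank_counts <- counts
  probes
}

# Occurrences of `pat` in `x` on either strand (exact, possibly
# overlapping).
count_occurrences <- function(x, pat) {
  n_fwd <- length(Biostrings::matchPattern(pat, Biostrings::DNAString(x)))
  n_rev <- length(Biostrings::matchPattern(revcomp(pat), Biostrings::DNAString(x)))
  n_fwd + n_rev
}

#' Call presence/absence of one insertion site from evidence
#'
#' Probe support mirrors flank re-assembly logic: a site is `present` when
#' both junction probes are supported and the empty-site probe is not;
#' `absent` when the empty-site probe is supported and the junctions are
#' not; anything else — contradictory evidence, a non-unique probe, or an
#' empty evidence source — is `ambiguous`.
#'
#' Read evidence supports a probe when the read contains the probe (or its
#' reverse complement) as an exact substring; at least `min_support` such
#' reads are required. Assembly evidence supports a probe when it occurs at
#' least once on either strand.
#'
#' @param probes output of [build_probes()].
#' @param evidence either a character vector of reads (length > 1, or wrap
#'   a single read in `list(reads = ...)`) or a single assembly string
#'   (or `list(assembly = ...)`).
#' @param min_support minimum supporting reads per probe (default 3).
#' @return one-row tibble of class `diff_call`: verdict, left_support,
#'   right_support, empty_support, probe_unique.
#' @export
call_presence <- function(probes, evidence, min_support = 3) {
  mode <- NULL
  if (is.list(evidence) && !is.null(evidence$reads)) {
    reads <- evidence$reads; mode <- "reads"
  } else if (is.list(evidence) && !is.null(evidence$assembly)) {
    asm <- evidence$assembly; mode <- "assembly"
  } else if (is.character(evidence) && length(evidence) > 1) {
    reads <- evidence; mode <- "reads"
  } else if (is.character(evidence) && length(evidence) == 1) {
    asm <- evidence; mode <- "assembly"
  } else stop("evidence must be a read vector or an assembly string")

  support <- function(p) {
    if (mode == "reads") {
      if (length(reads) == 0) return(0L)
      sum(grepl(p, reads, fixed = TRUE) | grepl(revcomp(p), reads, fixed = TRUE))
    } else {
      if (nchar(asm) == 0) return(0L)
      count_occurrences(asm, p)
    }
  }
  ls <- support(probes$left)
  rs <- support(probes$right)
  es <- support(probes$empty)
  thr <- if (mode == "reads") min_support else 1L
  empty_source <- (mode == "reads" && length(reads) == 0) ||
    (mode == "assembly" && nchar(asm) == 0)
  verdict <- if (empty_source || !isTRUE(probes$probe_unique)) {
    "ambiguous"
  } else if (ls >= thr && rs >= thr && es == 0) {
    "present"
  } else if (es >= thr && ls == 0 && rs == 0) {
    "absent"
  } else {
    "ambiguous"
  }
  out <- tibble::tibble(verdict = verdict, left_support = as.integer(ls),
                        right_support = as.integer(rs),
                        empty_support = as.integer(es),
                        probe_unique = isTRUE(probes$probe_unique))
  class(out) <- c("diff_call", class(out))
  out
}

#' Presence/absence matrix of insertion sites across evidence sources
#'
#' Builds probes for every copy in the backbone and calls each site against
#' each evidence source. Sites absent in every source are the ones unique
#' to the backbone genome.
#'
#' @param genome backbone DNA string.
#' @param copies `is_copies` or truth tibble with start, end and a
#'   tsd_len column (or a `tsds` table joined by copy_id).
#' @param evidence_list named list of evidence sources (read vectors or
#'   assembly strings, see [call_presence()]).
#' @param tsds optional [detect_tsds()] output supplying dr_len per
#'   copy_id when `copies` lacks tsd_len.
#' @param probe_flank,min_support see [build_probes()], [call_presence()].
#' @param circular logical.
#' @return list of class `mobilome_diff`: `calls` (long tibble: copy_id,
#'   source, verdict, supports), `matrix` (wide tibble copy_id x source),
#'   `unique_to_backbone` (copy ids absent from every source).
#' @export
diff_mobilomes <- function(genome, copies, evidence_list, tsds = NULL,
                           probe_flank = 30, min_support = 3,
                           circular = FALSE) {
  stopifnot(length(evidence_list) > 0, !is.null(names(evidence_list)))
  ids <- if ("copy_id" %in% names(copies)) copies$copy_id
         else sprintf("c%03d", seq_len(nrow(copies)))
  tsd_len <- if ("tsd_len" %in% names(copies)) {
    copies$tsd_len
  } else if (!is.null(tsds)) {
    tsds$dr_len[match(ids, tsds$copy_id)]
  } else stop("supply tsd_len in `copies` or a `tsds` table")
  rows <- list()
  for (i in seq_len(nrow(copies))) {
    pr <- build_probes(genome, copies$start[i], copies$end[i], tsd_len[i],
                       probe_flank = probe_flank, all_copies = copies,
                       circular = circular)
    for (src in names(evidence_list)) {
      call <- call_presence(pr, evidence_list[[src]], min_support)
      call$copy_id <- ids[i]
      call$source <- src
      rows[[length(rows) + 1L]] <- call
    }
  }
  calls <- do.call(rbind, rows)
  calls <- calls[, c("copy_id", "source", "verdict", "left_support",
                     "right_support", "empty_support", "probe_unique")]
  wide <- tibble::tibble(copy_id = ids)
  for (src in names(evidence_list)) {
    wide[[src]] <- calls$verdict[calls$source == src][match(ids, calls$copy_id[calls$source == src])]
  }
  absent_everywhere <- vapply(ids, function(id) {
    all(calls$verdict[calls$copy_id == id] == "absent")
  }, logical(1))
  structure(list(calls = calls, matrix = wide,
                 unique_to_backbone = ids[absent_everywhere]),
            class = "mobilome_diff")
}

#' @export
print.mobilome_diff <- function(x, ...) {
  cat(sprintf("<mobilome_diff> %d sites x %d sources; %d unique to backbone\n",
              nrow(x$matrix), ncol(x$matrix) - 1L,
              length(x$unique_to_backbone)))
  invisible(x)
}
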