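#' @importFrom Biostrings PDict matchPDict pairwiseAlignment pattern subject
#'   nucleotideSubstitutionMatrix
NULL

# ---- seeding -----------------------------------------------------------

.pdict_cache <- new.env(parent = emptyenv())

# Exact k-mer seed hits of `pat` in `subj_ds` (a DNAString). Returns a
# data.frame of genome position, pattern position and implied offset
# (genome_pos - pattern_pos) for every exact k-mer match. Seeds are taken
# every `stride` positions; the PDict index is cached per pattern.
seed_offsets <- function(subj_ds, pat, k = 13, stride = 2) {
  L <- nchar(pat)
  if (L < k) return(data.frame(gpos = integer(0), ppos = integer(0), off = integer(0)))
  starts <- seq(1L, L - k + 1L, by = stride)
  key <- paste0(k, ":", stride, ":", L, ":", substr(pat, 1, 40), ":",
                substr(pat, L - 39, L))
  pd <- .pdict_cache[[key]]
  if (is.null(pd)) {
    kmers <- Biostrings::DNAStringSet(substring(pat, starts, starts + k - 1))
    pd <- Biostrings::PDict(kmers)
    .pdict_cache[[key]] <- pd
  }
  m <- Biostrings::matchPDict(pd, subj_ds)
  st <- Biostrings::startIndex(m)
  lens <- lengths(st)
  gpos <- unlist(st, use.names = FALSE)
  if (is.null(gpos)) gpos <- integer(0)
  ppos <- rep.int(starts, lens)
  data.frame(gpos = gpos, ppos = ppos, off = gpos - ppos)
}

# Group seed offsets into candidate loci: offsets within `gap_tol` of each
# other belong to one candidate (tolerates small indels).
cluster_offsets <- function(seeds, gap_tol = 30L, min_support = 3L) {
  if (nrow(seeds) == 0) return(list())
  seeds <- seeds[order(seeds$off), ]
  grp <- cumsum(c(1L, diff(seeds$off) > gap_tol))
  out <- lapply(split(seeds, grp), function(s) {
    tab <- sort(table(s$off), decreasing = TRUE)
    list(offset = as.integer(names(tab)[1]),
         top_offsets = as.integer(names(tab)[seq_len(min(3, length(tab)))]),
         support = nrow(s),
         off_spread = diff(range(s$off)),
         gmin = min(s$gpos), gmax = max(s$gpos))
  })
  Filter(function(x) x$support >= min_support, out)
}

# ---- verification ------------------------------------------------------

# Verify a candidate offset by direct position-wise comparison under the
# substitution-only divergence model. Returns NULL or a hit record with the
# copy span in gx coordinates. Full-length copies are reported as the full
# projected reference span; partial copies as the maximal high-identity run.
verify_offset <- function(gx, pat, offset, min_identity, min_coverage,
                          end_window = 40L, end_thresh = 0.45,
                          run_window = 31L, run_thresh = 0.5) {
  L <- nchar(pat)
  glen <- nchar(gx)
  a <- max(1L, offset + 1L)
  b <- min(glen, offset + L)
  if (b - a + 1 < 50) return(NULL)
  pa <- a - offset          # pattern coords of the comparable slice
  pb <- b - offset
  gseq <- substr(gx, a, b)
  pseq <- substr(pat, pa, pb)
  match_vec <- charToRaw(gseq) == charToRaw(pseq)
  n <- length(match_vec)
  ident_all <- mean(match_vec)
  ew <- min(end_window, n)
  left_ok <- mean(match_vec[seq_len(ew)]) >= end_thresh
  right_ok <- mean(match_vec[seq.int(n - ew + 1L, n)]) >= end_thresh
  if (ident_all >= min_identity && left_ok && right_ok) {
    return(list(start = a, end = b, identity = ident_all,
                coverage = n / L, pat_range = c(pa, pb)))
  }
  # partial copy: longest run of windows above run_thresh
  if (n <= run_window) return(NULL)
  cs <- cumsum(c(0L, as.integer(match_vec)))
  wid <- (cs[(run_window + 1):(n + 1)] - cs[1:(n - run_window + 1)]) / run_window
  mask <- wid >= run_thresh
  if (!any(mask)) return(NULL)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]
  ra <- starts[best]
  rb <- ends[best] + run_window - 1L
  # shrink window-quantized ends until the terminal 10-mers look like
  # element (not flank), then trim to matching bases
  while (rb - ra > 10 && mean(match_vec[max(ra, rb - 9L):rb]) < 0.6) rb <- rb - 1L
  while (rb - ra > 10 && mean(match_vec[ra:min(rb, ra + 9L)]) < 0.6) ra <- ra + 1L
  while (ra <= rb && !match_vec[ra]) ra <- ra + 1L
  while (rb >= ra && !match_vec[rb]) rb <- rb - 1L
  if (rb - ra + 1 < 50) return(NULL)
  ident_run <- mean(match_vec[ra:rb])
  cov <- (rb - ra + 1) / L
  if (ident_run < min_identity || cov < min_coverage) return(NULL)
  list(start = a + ra - 1L, end = a + rb - 1L, identity = ident_run,
       coverage = cov, pat_range = c(pa + ra - 1L, pa + rb - 1L))
}

# Upper bound on the achievable identity of an indel-bearing candidate:
# positions matching under any of the cluster's top offsets. Cheap gate in
# front of the dynamic-programming fallback.
combined_offset_identity <- function(gx, pat, offsets) {
  L <- nchar(pat)
  glen <- nchar(gx)
  best <- NULL
  for (off in offsets) {
    a <- max(1L, off + 1L); b <- min(glen, off + L)
    if (b - a + 1 < 50) next
    v <- logical(L)
    v[(a - off):(b - off)] <-
      charToRaw(substr(gx, a, b)) == charToRaw(substr(pat, a - off, b - off))
    best <- if (is.null(best)) v else best | v
  }
  if (is.null(best)) 0 else mean(best)
}

# Local-alignment fallback for candidates the substitution-only check
# rejects (e.g. indel-bearing copies). pairwiseAlignment is only the rescue
# path here; the primary path is the offset projection above. The window is
# the projected span under the cluster's offsets plus a margin.
align_fallback <- function(gx, pat, offsets, min_identity, min_coverage) {
  L <- nchar(pat)
  wa <- max(1L, min(offsets) + 1L - 50L)
  wb <- min(nchar(gx), max(offsets) + L + 50L)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pat),
    Biostrings::DNAString(substr(gx, wa, wb)),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3),
    gapOpening = 5, gapExtension = 2
  )
  pr <- aln@pattern@range
  sr <- aln@subject@range
  cov <- pr@width / L
  ident <- Biostrings::pid(aln, type = "PID1") / 100
  if (ident < min_identity || cov < min_coverage) return(NULL)
  list(start = wa + sr@start - 1L, end = wa + sr@start + sr@width - 2L,
       identity = ident, coverage = cov,
       pat_range = c(pr@start, pr@start + pr@width - 1L))
}

# ---- the scanner -------------------------------------------------------

empty_copies <- function() {
  out <- tibble::tibble(
    copy_id = character(0), replicon = character(0), start = integer(0),
    end = integer(0), wraps = logical(0), orientation = character(0),
    is_id = character(0), ref_id = character(0), identity = numeric(0),
    coverage = numeric(0), support = integer(0)
  )
  class(out) <- c("is_copies", class(out))
  out
}

#' Find IS copies in a genome by reference-based seed-and-extend
#'
#' Scans both strands of a genome for copies of each reference element.
#' Exact k-mer seeds vote for a candidate diagonal (offset); each candidate
#' is verified by direct position-wise comparison of the projected
#' reference span against the genome (the copy boundaries are the aligned
#' reference span projected onto the genome; the directed repeats fall
#' outside the copy). Indel-bearing candidates that fail the
#' substitution-only check are rescued by banded local alignment.
#' Overlapping hits to the same locus are merged keeping the best identity;
#' on circular replicons copies may wrap the origin (reported with
#' end < start and `wraps = TRUE`).
#'
#' @param genome DNA string (one replicon).
#' @param refs named list of `is_reference` objects (or DNA strings); each
#'   must be at least 100 bp.
#' @param min_identity,min_coverage acceptance thresholds in (0, 1].
#' @param k seed k-mer length.
#' @param circular logical; when TRUE the scan crosses the origin.
#' @param replicon replicon name used in the output.
#' @param classify when TRUE (default) each copy is assigned a variant
#'   label via [classify_variant()].
#' @return tibble of class `is_copies`, sorted by start: copy_id, replicon,
#'   start, end, wraps, orientation ("Forward"/"Reverse"), is_id (variant
#'   label), ref_id (best reference), identity, coverage, support.
#' @export
find_is_copies <- function(genome, refs, min_identity = 0.7,
                           min_coverage = 0.8, k = 13, circular = FALSE,
                           replicon = "seq", classify = TRUE) {
  if (length(refs) == 0) stop("refs must be non-empty")
  if (is.null(names(refs)))
    names(refs) <- vapply(refs, function(r)
      if (inherits(r, "is_reference")) r$id else "ref", character(1))
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  ref_seqs <- lapply(refs, ref_sequence)
  if (any(nchar(ref_seqs) < 100))
    stop("degenerate reference shorter than 100 bp")
  glen <- nchar(genome)
  if (glen == 0) return(empty_copies())
  max_l <- max(nchar(ref_seqs))
  gx <- if (circular) paste0(genome, substr(genome, 1, min(glen, max_l + 50))) else genome
  subj_ds <- Biostrings::DNAString(gx)

  hits <- list()
  pending <- list()
  for (rid in names(ref_seqs)) {
    rs <- ref_seqs[[rid]]
    for (strand in c("Forward", "Reverse")) {
      pat <- if (strand == "Forward") rs else revcomp(rs)
      seeds <- seed_offsets(subj_ds, pat, k = k)
      for (cand in cluster_offsets(seeds)) {
        h <- verify_offset(gx, pat, cand$offset, min_identity, min_coverage)
        if (!is.null(h)) {
          h$ref_id <- rid
          h$orientation <- strand
          h$support <- cand$support
          hits[[length(hits) + 1L]] <- h
        } else if (cand$support >= 10) {
          ub <- combined_offset_identity(gx, pat, cand$top_offsets)
          if (ub >= min_identity - 0.02) {
            pending[[length(pending) + 1L]] <- list(
              pat = pat, offsets = cand$top_offsets, ub = ub, ref_id = rid,
              orientation = strand, support = cand$support)
          }
        }
      }
    }
  }
  # alignment fallback only for candidate loci not already explained by a
  # better direct hit (avoids re-aligning every locus against every
  # indel-bearing reference)
  for (p in pending) {
    span <- c(min(p$offsets) + 1L, max(p$offsets) + nchar(p$pat))
    explained <- any(vapply(hits, function(h) {
      ov <- min(h$end, span[2]) - max(h$start, span[1]) + 1
      ov > 0.5 * (span[2] - span[1] + 1) && h$identity >= p$ub
    }, logical(1)))
    if (explained) next
    h <- align_fallback(gx, p$pat, p$offsets, min_identity, min_coverage)
    if (!is.null(h)) {
      h$ref_id <- p$ref_id
      h$orientation <- p$orientation
      h$support <- p$support
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (length(hits) == 0) return(empty_copies())
  ht <- tibble::tibble(
    start = vapply(hits, `[[`, integer(1), "start"),
    end = vapply(hits, `[[`, integer(1), "end"),
    orientation = vapply(hits, `[[`, character(1), "orientation"),
    ref_id = vapply(hits, `[[`, character(1), "ref_id"),
    identity = vapply(hits, `[[`, numeric(1), "identity"),
    coverage = vapply(hits, `[[`, numeric(1), "coverage"),
    support = vapply(hits, function(h) as.integer(h$support), integer(1))
  )
  if (circular) {
    # drop duplicates that live entirely in the appended origin-crossing pad
    ht <- ht[ht$start <= glen, , drop = FALSE]
    # drop partial re-detections of a wrapping copy's tail at the origin
    wrap_rows <- which(ht$end > glen)
    if (length(wrap_rows) > 0) {
      drop <- rep(FALSE, nrow(ht))
      for (w in wrap_rows) {
        tail_end <- ht$end[w] - glen
        drop <- drop | (ht$end <= glen & ht$start <= tail_end)
      }
      drop[wrap_rows] <- FALSE
      ht <- ht[!drop, , drop = FALSE]
    }
  }
  ht <- merge_locus_hits(ht)
  ht <- ht[order(ht$start), , drop = FALSE]

  wraps <- circular & ht$end > glen
  copy_seq <- character(nrow(ht))
  for (i in seq_len(nrow(ht))) {
    s <- wrap_substr(gx, ht$start[i], ht$end[i], circular = FALSE)
    copy_seq[i] <- if (ht$orientation[i] == "Reverse") revcomp(s) else s
  }
  labels <- ht$ref_id
  idents <- ht$identity
  if (classify) {
    cl <- classify_variants(copy_seq, refs)
    labels <- cl$label
    idents <- cl$identity
  }
  out <- tibble::tibble(
    copy_id = sprintf("%s_c%03d", replicon, seq_len(nrow(ht))),
    replicon = replicon,
    start = ht$start,
    end = ifelse(wraps, ht$end - glen, ht$end),
    wraps = wraps,
    orientation = ht$orientation,
    is_id = labels,
    ref_id = ht$ref_id,
    identity = idents,
    coverage = ht$coverage,
    support = ht$support
  )
  class(out) <- c("is_copies", class(out))
  out
}

# Merge hits that describe the same locus: keep the best-identity hit among
# hits whose spans overlap by more than half of the shorter span, or that
# hit the same reference/strand within 50 bp of each other.
merge_locus_hits <- function(ht) {
  if (nrow(ht) <= 1) return(ht)
  ht <- ht[order(-ht$identity, -ht$coverage), , drop = FALSE]
  keep <- rep(TRUE, nrow(ht))
  for (i in seq_len(nrow(ht))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(ht))) {
      if (j == i || !keep[j]) next
      ov <- min(ht$end[i], ht$end[j]) - max(ht$start[i], ht$start[j]) + 1
      short <- min(ht$end[i] - ht$start[i], ht$end[j] - ht$start[j]) + 1
      same_locus <- ov > 0.5 * short
      adjacent <- ht$ref_id[i] == ht$ref_id[j] &&
        ht$orientation[i] == ht$orientation[j] &&
        ov <= 0 && (max(ht$start[i], ht$start[j]) -
                      min(ht$end[i], ht$end[j])) < 50
      if (same_locus || adjacent) keep[j] <- FALSE
    }
  }
  ht[keep, , drop = FALSE]
}

#' Extract the sequence of a detected copy
#'
#' Wrap-aware extraction of a copy's sequence in element orientation
#' (Reverse copies are reverse-complemented).
#'
#' @param genome replicon DNA string.
#' @param copy one-row slice of an `is_copies` tibble.
#' @param circular logical.
#' @return DNA string.
#' @export
copy_sequence <- function(genome, copy, circular = FALSE) {
  len <- nchar(genome)
  end <- if (isTRUE(copy$wraps)) copy$end + len else copy$end
  s <- wrap_substr(genome, copy$start, end, circular = circular || copy$wraps)
  if (copy$orientation == "Reverse") revcomp(s) else s
}

# ---- variant classification -------------------------------------------

# Identity of a copy sequence against one reference: exact Hamming identity
# for equal lengths (the substitution-only model), overlap alignment
# otherwise.
variant_identity <- function(copy_seq, ref_seq) {
  if (nchar(copy_seq) == nchar(ref_seq))
    return(hamming_identity(copy_seq, ref_seq))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(copy_seq), Biostrings::DNAString(ref_seq),
    type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3),
    gapOpening = 5, gapExtension = 2
  )
  Biostrings::pid(aln, type = "PID3") / 100
}

#' Classify a copy sequence into a variant label
#'
#' The label is the reference giving the highest identity. A copy at or
#' above `same_variant` identity (default 99%) to a reference takes that
#' reference's label; below the family floor (default 70%, mirroring a
#' BLAST-style >70% cut-off) it is labelled "unidentified"; in between it
#' founds a new variant centroid named after the nearest reference.
#'
#' @param copy_seq DNA string of the copy (element orientation).
#' @param refs named list of `is_reference` or DNA strings.
#' @param same_variant,family_floor identity thresholds.
#' @return list(label, identity, ref_id).
#' @export
classify_variant <- function(copy_seq, refs, same_variant = 0.99,
                             family_floor = 0.70) {
  cl <- classify_variants(copy_seq, refs, same_variant, family_floor)
  list(label = cl$label[1], identity = cl$identity[1], ref_id = cl$ref_id[1])
}

# Vectorized classification with new-centroid clustering across the set.
# Unequal-length comparisons are gated by a cheap shift-combined identity
# upper bound; the alignment-based identity is only computed when such a
# centroid could actually win.
classify_variants <- function(copy_seqs, refs, same_variant = 0.99,
                              family_floor = 0.70) {
  ref_seqs <- lapply(refs, ref_sequence)
  centroids <- ref_seqs
  labels <- character(length(copy_seqs))
  idents <- numeric(length(copy_seqs))
  ref_ids <- character(length(copy_seqs))
  n_new <- 0L
  for (i in seq_along(copy_seqs)) {
    cs <- copy_seqs[i]
    exact <- vapply(centroids, function(r) nchar(r) == nchar(cs), logical(1))
    ids <- vapply(centroids, function(r) {
      if (nchar(r) == nchar(cs)) {
        hamming_identity(cs, r)
      } else {
        d <- nchar(r) - nchar(cs)
        long <- if (d > 0) r else cs
        short <- if (d > 0) cs else r
        combined_offset_identity(long, short, c(0L, abs(d)))
      }
    }, numeric(1))
    while (!exact[which.max(ids)]) {
      j <- which.max(ids)
      ids[j] <- variant_identity(cs, centroids[[j]])
      exact[j] <- TRUE
    }
    while (!exact[which.max(ids[seq_along(ref_seqs)])]) {
      j <- which.max(ids[seq_along(ref_seqs)])
      ids[j] <- variant_identity(cs, centroids[[j]])
      exact[j] <- TRUE
    }
    best <- which.max(ids)
    best_ref <- which.max(ids[seq_along(ref_seqs)])
    idents[i] <- ids[best_ref]
    ref_ids[i] <- names(ref_seqs)[best_ref]
    if (ids[best] >= same_variant) {
      labels[i] <- names(centroids)[best]
    } else if (ids[best_ref] >= family_floor) {
      n_new <- n_new + 1L
      lab <- sprintf("%s_v%d", names(ref_seqs)[best_ref], n_new + 1L)
      centroids[[lab]] <- copy_seqs[i]
      labels[i] <- lab
    } else {
      labels[i] <- "unidentified"
    }
  }
  tibble::tibble(label = labels, identity = idents, ref_id = ref_ids)
}

# ---- ORF integrity -----------------------------------------------------

#' Check ORF integrity of a detected copy
#'
#' Projects each reference ORF onto the copy and calls its status:
#' `intact` (start codon, terminal stop, no internal stop in the projected
#' frame), `frameshift` (net indel not divisible by 3 inside the ORF),
#' `premature_stop` (in-frame internal stop, or a damaged start/stop codon
#' without indel), `absent` (the ORF region is missing, e.g. truncated
#' away). Equal-length copies are projected directly under the
#' substitution-only model; copies with length differences are mapped
#' through a global alignment. An unalignable copy returns all ORFs
#' `absent` with attribute `low_confidence = TRUE`.
#'
#' @param copy_seq copy sequence in element orientation.
#' @param ref an `is_reference` with `orf_models`.
#' @param start_codons accepted initiator codons.
#' @return named character vector of statuses (names = ORF roles).
#' @export
check_orf_integrity <- function(copy_seq, ref,
                                start_codons = c("ATG", "GTG", "TTG")) {
  stopifnot(inherits(ref, "is_reference"))
  orfs <- ref$orf_models
  statuses <- stats::setNames(rep("absent", nrow(orfs)), orfs$role)
  L <- nchar(ref$sequence)
  n <- nchar(copy_seq)
  if (n == L) {
    map <- seq_len(L)  # identity projection, no indels
    covered <- rep(TRUE, L)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(ref$sequence), Biostrings::DNAString(copy_seq),
      type = "overlap",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3),
      gapOpening = 5, gapExtension = 2
    )
    if (Biostrings::pid(aln, type = "PID1") < 40) {
      attr(statuses, "low_confidence") <- TRUE
      return(statuses)
    }
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    p_pos <- cumsum(p != "-") + (aln@pattern@range@start - 1L)
    s_pos <- cumsum(s != "-") + (aln@subject@range@start - 1L)
    map <- rep(NA_integer_, L)
    covered <- rep(FALSE, L)
    sel <- p != "-"
    map[p_pos[sel]] <- ifelse(s[sel] != "-", s_pos[sel], NA_integer_)
    covered[p_pos[sel]] <- s[sel] != "-"
  }
  for (i in seq_len(nrow(orfs))) {
    a <- orfs$start[i]; b <- orfs$end[i]
    cov <- mean(covered[a:b])
    if (is.na(cov) || cov < 0.5) { statuses[i] <- "absent"; next }
    cpos <- map[a:b]
    cpos <- cpos[!is.na(cpos)]
    if (length(cpos) == 0) { statuses[i] <- "absent"; next }
    seg_start <- min(cpos); seg_end <- max(cpos)
    seg_len <- seg_end - seg_start + 1L
    orf_len <- b - a + 1L
    # partial projection at the ends = truncation into the ORF
    if (sum(covered[a:b]) < 0.9 * orf_len &&
        (is.na(map[a]) || is.na(map[b]))) { statuses[i] <- "absent"; next }
    net <- seg_len - orf_len
    if (net %% 3 != 0) { statuses[i] <- "frameshift"; next }
    seg <- substr(copy_seq, seg_start, seg_end)
    ncod <- nchar(seg) %/% 3
    codons <- substring(seg, seq(1, by = 3, length.out = ncod),
                        seq(3, by = 3, length.out = ncod))
    has_start <- codons[1] %in% start_codons
    has_stop <- codons[ncod] %in% STOP_CODONS
    internal_stop <- any(codons[-ncod] %in% STOP_CODONS)
    statuses[i] <- if (has_start && has_stop && !internal_stop) "intact"
                   else "premature_stop"
  }
  statuses
}
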