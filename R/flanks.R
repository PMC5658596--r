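#' Detect the target-site duplication flanking a copy
#'
#' Reports the largest k in \[kmin, kmax\] such that the k bases immediately
#' 5' of the copy equal the k bases immediately 3' of it (exact match, the
#' longest-k rule; observed directed repeats are exact duplications of 5-8
#' bp with 7 bp dominant). `dr_len` is 0 when no k qualifies. A copy at the
#' edge of a linear replicon with insufficient flank is flagged
#' (`flank_ok = FALSE`, `dr_len = NA`) — distinct from a genuine 0.
#'
#' @param genome replicon DNA string.
#' @param start,end copy coordinates (1-based inclusive, repeats excluded).
#' @param kmin,kmax search range (defaults 4 and 12).
#' @param circular logical; flanks wrap the origin when TRUE.
#' @param wraps logical; TRUE when the copy itself spans the origin
#'   (end < start as stored); flanks are then taken wrap-aware.
#' @return one-row tibble: dr_len, dr_seq, kmin, kmax, flank_ok.
#' @export
detect_tsd <- function(genome, start, end, kmin = 4, kmax = 12,
                       circular = FALSE, wraps = FALSE) {
  stopifnot(kmin >= 1, kmax >= kmin)
  len <- nchar(genome)
  if (wraps && !circular) stop("a wrapping copy requires a circular replicon")
  end_u <- if (wraps) end + len else end  # unwrapped end coordinate
  if (!circular && (start - kmin < 1 || end_u + kmin > len)) {
    return(tibble::tibble(dr_len = NA_integer_, dr_seq = NA_character_,
                          kmin = kmin, kmax = kmax, flank_ok = FALSE))
  }
  kmax_eff <- if (circular) kmax else min(kmax, start - 1, len - end_u)
  left <- wrap_substr(genome, start - kmax_eff, start - 1, circular = circular)
  right <- wrap_substr(genome, end_u + 1, end_u + kmax_eff, circular = circular)
  dr_len <- 0L
  dr_seq <- ""
  for (k in seq(kmax_eff, kmin)) {
    if (substr(left, kmax_eff - k + 1, kmax_eff) == substr(right, 1, k)) {
      dr_len <- as.integer(k)
      dr_seq <- substr(right, 1, k)
      break
    }
  }
  tibble::tibble(dr_len = dr_len, dr_seq = dr_seq, kmin = kmin, kmax = kmax,
                 flank_ok = TRUE)
}

#' Target-site duplications for a table of copies
#'
#' @param genome replicon DNA string.
#' @param copies `is_copies` tibble (or any tibble with start, end, wraps).
#' @inheritParams detect_tsd
#' @return tibble with copy_id and the [detect_tsd()] columns per copy.
#' @export
detect_tsds <- function(genome, copies, kmin = 4, kmax = 12,
                        circular = FALSE) {
  rows <- lapply(seq_len(nrow(copies)), function(i) {
    r <- detect_tsd(genome, copies$start[i], copies$end[i], kmin, kmax,
                    circular = circular,
                    wraps = isTRUE(copies$wraps[i]))
    r$copy_id <- if ("copy_id" %in% names(copies)) copies$copy_id[i]
                 else sprintf("c%03d", i)
    r
  })
  out <- do.call(rbind, rows)
  out[, c("copy_id", setdiff(names(out), "copy_id"))]
}

#' Detect terminal inverted repeats of an element
#'
#' Finds all maximal reverse-complement matches between the 5' window and
#' the 3' window of an element sequence: pairs of equal-length spans
#' (left in the 5' window, right in the 3' window, element-local 1-based
#' coordinates) where the left span equals the reverse complement of the
#' right span up to `floor(max_mismatch_frac * length)` mismatches. Matches
#' are maximal (extending either end would break the mismatch budget or
#' leave the windows) and are reported sorted by length descending, then
#' leftmost.
#'
#' @param element_seq element DNA string.
#' @param window terminal window length (at most half the element).
#' @param min_len minimum reported repeat length.
#' @param max_mismatch_frac allowed mismatch fraction of the repeat length.
#' @return tibble: left_start, left_end, right_start, right_end, length,
#'   mismatches.
#' @export
detect_irs <- function(element_seq, window = 150, min_len = 10,
                       max_mismatch_frac = 0) {
  L <- nchar(element_seq)
  if (window > L / 2) stop("window larger than half the element")
  stopifnot(min_len >= 2, max_mismatch_frac >= 0, max_mismatch_frac < 1)
  w1 <- substr(element_seq, 1, window)
  w2 <- substr(element_seq, L - window + 1, L)
  r <- revcomp(w2)   # r[p] corresponds to element position L - p + 1
  a <- charToRaw(w1)
  b <- charToRaw(r)
  res <- list()
  for (d in seq(-(window - 1), window - 1)) {
    # diagonal: w1[i] vs r[i + d]
    i_lo <- max(1L, 1L - d)
    i_hi <- min(window, window - d)
    if (i_hi - i_lo + 1 < min_len) next
    idx <- i_lo:i_hi
    v <- a[idx] == b[idx + d]
    runs <- maximal_budget_runs(v, max_mismatch_frac, min_len)
    for (rn in runs) {
      i1 <- idx[rn[1]]; i2 <- idx[rn[2]]
      p1 <- i1 + d; p2 <- i2 + d
      res[[length(res) + 1L]] <- c(
        left_start = i1, left_end = i2,
        right_start = L - p2 + 1L, right_end = L - p1 + 1L,
        length = i2 - i1 + 1L, mismatches = rn[3]
      )
    }
  }
  if (length(res) == 0)
    return(tibble::tibble(left_start = integer(0), left_end = integer(0),
                          right_start = integer(0), right_end = integer(0),
                          length = integer(0), mismatches = integer(0)))
  out <- tibble::as_tibble(as.data.frame(do.call(rbind, res)))
  out <- out[order(-out$length, out$left_start), ]
  out
}

# Maximal runs in a logical vector allowing at most floor(frac * len)
# mismatches; runs start and end on matches, and a run whose extension stays
# within budget is dominated and dropped. Returns list of
# c(start, end, mismatches) (indices into v).
maximal_budget_runs <- function(v, frac, min_len) {
  n <- length(v)
  runs <- list()
  if (frac == 0) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values & r$lengths >= min_len))
      runs[[length(runs) + 1L]] <- c(starts[i], ends[i], 0L)
    return(runs)
  }
  mm <- cumsum(!v)
  best_end <- 0L
  for (s in seq_len(n)) {
    # a run starting on a match preceded by a match is dominated
    if (!v[s] || (s > 1 && v[s - 1])) next
    if (s + min_len - 1L > n) break
    e_best <- 0L
    # budget grows with length, so take the largest feasible end
    for (e2 in seq(n, s + min_len - 1L)) {
      if (!v[e2]) next
      bad <- mm[e2] - (if (s > 1) mm[s - 1] else 0L)
      if (bad <= floor(frac * (e2 - s + 1L))) { e_best <- e2; break }
    }
    if (e_best >= s + min_len - 1L && e_best > best_end) {
      bad <- mm[e_best] - (if (s > 1) mm[s - 1] else 0L)
      runs[[length(runs) + 1L]] <- c(s, e_best, as.integer(bad))
      best_end <- e_best
    }
  }
  runs
}

#' Positional information content of insertion-site flanks
#'
#' Computes per-position information content (2 minus the Shannon entropy
#' of base frequencies, in bits) over a set of equal-length flank
#' sequences, with a Miller–Madow small-sample correction of
#' 3 / (2 ln(2) n) bits subtracted per position. The verdict is
#' "no consensus" unless some window of `window` consecutive positions has
#' mean corrected IC above `ic_threshold` — the test used to ask whether an
#' element shows a preferred insertion-site motif.
#'
#' @param flanks character vector (>= 5) of equal-length DNA strings.
#' @param ic_threshold mean-IC threshold in bits (default 1.0).
#' @param window window length in positions (default 4).
#' @return list: `ic` (corrected per-position IC), `ic_raw`, `verdict`
#'   ("consensus"/"no consensus"), `window_start` (position of the
#'   highest-mean window), `window_mean`.
#' @export
flank_conservation <- function(flanks, ic_threshold = 1.0, window = 4) {
  n <- length(flanks)
  if (n < 5) stop("need at least 5 flank sequences")
  lens <- nchar(flanks)
  if (length(unique(lens)) != 1) stop("flank sequences must be equal length")
  L <- lens[1]
  if (L < window) stop("flanks shorter than the scan window")
  m <- do.call(rbind, strsplit(flanks, "", fixed = TRUE))
  ic_raw <- apply(m, 2, function(col) {
    p <- table(factor(col, levels = DNA_BASES)) / length(col)
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  corr <- 3 / (2 * log(2) * n)
  ic <- ic_raw - corr
  means <- stats::filter(ic, rep(1 / window, window), sides = 1)
  means <- means[!is.na(means)]
  best <- which.max(means)
  list(
    ic = as.numeric(ic),
    ic_raw = as.numeric(ic_raw),
    verdict = if (max(means) > ic_threshold) "consensus" else "no consensus",
    window_start = as.integer(best),
    window_mean = as.numeric(max(means))
  )
}
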