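#' Variant census of a mobilome table
#'
#' @param x tibble with a `variant` (or `is_id`) column.
#' @return tibble(variant, n) sorted by copy number descending then name.
#' @export
variant_census <- function(x) {
  v <- if ("variant" %in% names(x)) x$variant else x$is_id
  tab <- table(v)
  out <- tibble::tibble(variant = as.character(names(tab)),
                        n = as.integer(tab))
  out[order(-out$n, out$variant), ]
}

#' Directed-repeat length histogram
#'
#' @param x tibble with a `dr_len` (or `tsd_len`) column; NA (undetermined
#'   flank) entries are excluded.
#' @return tibble(dr_len, n) sorted by dr_len.
#' @export
dr_length_histogram <- function(x) {
  v <- if ("dr_len" %in% names(x)) x$dr_len else x$tsd_len
  v <- v[!is.na(v)]
  tab <- table(v)
  out <- tibble::tibble(dr_len = as.integer(as.character(names(tab))),
                        n = as.integer(tab))
  out[order(out$dr_len), ]
}

#' Presence-in-previous-sequences summary
#'
#' @param x tibble with a `presence_in_previous` column ("Yes"/"No") or a
#'   logical `in_previous` column.
#' @return named integer vector c(present, absent).
#' @export
presence_summary <- function(x) {
  v <- if ("presence_in_previous" %in% names(x)) {
    x$presence_in_previous == "Yes"
  } else x$in_previous
  c(present = sum(v), absent = sum(!v))
}

#' Full census of an insertion-record table
#'
#' One call computing every headline number of a mobilome survey table:
#' total copies, per-variant counts, DR-length histogram, context census
#' (with per-replicon in-gene disruptions) and the presence/absence split
#' against previous sequence data.
#'
#' @param records an `insertion_record` tibble from
#'   [load_insertion_table()] (or any tibble with the same columns).
#' @return list: n_total, variants (tibble), dr_hist (tibble), contexts
#'   (`context_census`), presence (named vector).
#' @export
mobilome_census <- function(records) {
  list(
    n_total = nrow(records),
    variants = variant_census(records),
    dr_hist = dr_length_histogram(records),
    contexts = summarize_contexts(records),
    presence = presence_summary(records)
  )
}

#' Assemble the per-copy mobilome report
#'
#' Joins detection, TSD, context and (optionally) presence/absence results
#' into one table with deterministic column order, plus the census tables.
#' All inputs must be keyed by the same copy ids; a key mismatch is an
#' error naming the offending copy.
#'
#' @param copies `is_copies` tibble.
#' @param tsds [detect_tsds()] output.
#' @param contexts [classify_contexts()] output (id column = copy ids).
#' @param diffs optional `mobilome_diff` object.
#' @return list of class `mobilome_report`: `table` (per-copy tibble),
#'   `variants`, `dr_hist`, `contexts` (census), `presence` (NULL without
#'   diffs).
#' @export
render_mobilome_report <- function(copies, tsds, contexts, diffs = NULL) {
  ids <- copies$copy_id
  check_keys <- function(k, what) {
    missing <- setdiff(ids, k)
    extra <- setdiff(k, ids)
    if (length(missing) > 0 || length(extra) > 0)
      stop(what, " keys do not match copies (first offender: ",
           c(missing, extra)[1], ")")
  }
  check_keys(tsds$copy_id, "tsds")
  check_keys(contexts$id, "contexts")
  tab <- tibble::tibble(
    copy_id = ids,
    replicon = copies$replicon,
    variant = copies$is_id,
    start = copies$start,
    end = copies$end,
    orientation = copies$orientation,
    identity = copies$identity,
    dr_seq = tsds$dr_seq[match(ids, tsds$copy_id)],
    dr_len = tsds$dr_len[match(ids, tsds$copy_id)],
    context_code = contexts$context_code[match(ids, contexts$id)],
    context_text = contexts$context_text[match(ids, contexts$id)]
  )
  presence <- NULL
  if (!is.null(diffs)) {
    check_keys(diffs$matrix$copy_id, "diffs")
    absent_all <- ids %in% diffs$unique_to_backbone
    tab$presence_in_previous <- ifelse(absent_all, "No", "Yes")
    presence <- presence_summary(tab)
  }
  ctx <- summarize_contexts(
    tibble::tibble(context_code = tab$context_code, replicon = tab$replicon))
  structure(list(table = tab, variants = variant_census(tab),
                 dr_hist = dr_length_histogram(tab), contexts = ctx,
                 presence = presence),
            class = "mobilome_report")
}

#' @export
print.mobilome_report <- function(x, ...) {
  cat(sprintf("<mobilome_report> %d copies, %d variants; DR lengths: %s\n",
              nrow(x$table), nrow(x$variants),
              paste(sprintf("%d:%d", x$dr_hist$dr_len, x$dr_hist$n),
                    collapse = " ")))
  invisible(x)
}
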