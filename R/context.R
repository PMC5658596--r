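#' Classify the genomic context of one insertion point
#'
#' The insertion point is the first base of the target-site duplication (the
#' disrupted position of the ancestral gene model). Codes follow the
#' three-way scheme of IS insertion-site surveys:
#' \describe{
#'   \item{a}{inside a gene (CDS or ncRNA feature; boundary-overlapping
#'     insertions count as in-gene) — the disrupted feature is reported;}
#'   \item{c}{within `promoter_window` bp upstream of a feature's start on
#'     its strand, and not inside any feature — the downstream feature is
#'     reported;}
#'   \item{b}{anything else (intergenic) — the two nearest flanking
#'     features are reported.}
#' }
#'
#' @param point 1-based insertion point in the coordinate system of
#'   `features` (the ancestral genome).
#' @param features tibble with columns feature_id, start, end, strand
#'   ("+"/"-"), and optionally product.
#' @param promoter_window bp upstream of a feature start counted as its
#'   promoter region (default 150).
#' @return list(context_code, affected_features (character vector of
#'   feature ids), context_text).
#' @export
classify_context <- function(point, features, promoter_window = 150) {
  if (is.null(features) || nrow(features) == 0) {
    warning("unannotated replicon: all insertions classified intergenic (b)")
    return(list(context_code = "b", affected_features = character(0),
                context_text = "unannotated"))
  }
  lab <- function(idx) {
    ids <- features$feature_id[idx]
    if ("product" %in% names(features)) {
      paste(features$product[idx], collapse = " - ")
    } else paste(ids, collapse = " - ")
  }
  inside <- which(features$start <= point & point <= features$end)
  if (length(inside) > 0) {
    return(list(context_code = "a",
                affected_features = features$feature_id[inside],
                context_text = lab(inside)))
  }
  up_plus <- features$strand == "+" &
    point >= features$start - promoter_window & point < features$start
  up_minus <- features$strand == "-" &
    point > features$end & point <= features$end + promoter_window
  upstream <- which(up_plus | up_minus)
  if (length(upstream) > 0) {
    d <- ifelse(features$strand[upstream] == "+",
                features$start[upstream] - point,
                point - features$end[upstream])
    nearest <- upstream[which.min(d)]
    return(list(context_code = "c",
                affected_features = features$feature_id[nearest],
                context_text = lab(nearest)))
  }
  left <- which(features$end < point)
  right <- which(features$start > point)
  nb <- c(
    if (length(left) > 0) left[which.max(features$end[left])],
    if (length(right) > 0) right[which.min(features$start[right])]
  )
  list(context_code = "b",
       affected_features = features$feature_id[nb],
       context_text = lab(nb))
}

#' Classify contexts for a table of insertions
#'
#' @param points integer vector of insertion points (first TSD base,
#'   ancestral coordinates).
#' @param features annotation tibble (see [classify_context()]).
#' @param promoter_window bp.
#' @param ids optional record ids.
#' @return tibble: id, point, context_code, context_text, affected
#'   (comma-separated feature ids).
#' @export
classify_contexts <- function(points, features, promoter_window = 150,
                              ids = NULL) {
  if (is.null(ids)) ids <- sprintf("site%03d", seq_along(points))
  rows <- lapply(seq_along(points), function(i) {
    cc <- classify_context(points[i], features, promoter_window)
    tibble::tibble(id = ids[i], point = points[i],
                   context_code = cc$context_code,
                   context_text = cc$context_text,
                   affected = paste(cc$affected_features, collapse = ","))
  })
  do.call(rbind, rows)
}

#' Census of insertion contexts
#'
#' Deterministic counts over a set of insertion records: totals by context
#' code, by replicon and code, in-gene disruptions per replicon, and the
#' number of insertions not disrupting an ORF (codes b + c).
#'
#' @param records tibble with columns context_code and replicon (an
#'   `insertion_record` table or a tibble assembled from
#'   [classify_contexts()] output).
#' @return list of class `context_census`: `by_code` (named counts),
#'   `by_replicon` (tibble replicon x code), `in_gene` (named per-replicon
#'   counts of code a), `n_in_gene`, `n_non_disrupting`, `n_total`.
#' @export
summarize_contexts <- function(records) {
  codes <- c("a", "b", "c")
  if (nrow(records) == 0) {
    return(structure(list(
      by_code = stats::setNames(rep(0L, 3), codes),
      by_replicon = tibble::tibble(replicon = character(0), a = integer(0),
                                   b = integer(0), c = integer(0)),
      in_gene = integer(0), n_in_gene = 0L, n_non_disrupting = 0L,
      n_total = 0L
    ), class = "context_census"))
  }
  stopifnot(all(records$context_code %in% codes))
  by_code <- vapply(codes, function(k) sum(records$context_code == k),
                    integer(1))
  reps <- unique(records$replicon)
  by_replicon <- tibble::tibble(
    replicon = reps,
    a = vapply(reps, function(r) sum(records$replicon == r &
                                       records$context_code == "a"), integer(1)),
    b = vapply(reps, function(r) sum(records$replicon == r &
                                       records$context_code == "b"), integer(1)),
    c = vapply(reps, function(r) sum(records$replicon == r &
                                       records$context_code == "c"), integer(1))
  )
  structure(list(
    by_code = by_code,
    by_replicon = by_replicon,
    in_gene = stats::setNames(by_replicon$a, by_replicon$replicon),
    n_in_gene = sum(by_code["a"]),
    n_non_disrupting = sum(by_code[c("b", "c")]),
    n_total = nrow(records)
  ), class = "context_census")
}

#' @export
print.context_census <- function(x, ...) {
  cat(sprintf("<context_census> %d insertions: %d in-gene (a), %d intergenic (b), %d promoter (c)\n",
              x$n_total, x$by_code["a"], x$by_code["b"], x$by_code["c"]))
  invisible(x)
}
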