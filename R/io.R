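#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ds <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ds), sub(" .*", "", names(ds)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  ds <- Biostrings::DNAStringSet(seqs)
  names(ds) <- names(seqs)
  Biostrings::writeXStringSet(ds, path)
  invisible(path)
}

# GRanges view of a copies table. Wrapping copies are clamped to the
# replicon end (an origin-crossing interval has no single-range
# representation), which is only used for track export.
copies_granges <- function(copies, replicon_lengths = NULL) {
  end <- copies$end
  if (any(copies$wraps)) {
    if (is.null(replicon_lengths))
      stop("replicon_lengths needed to export origin-wrapping copies")
    end[copies$wraps] <- replicon_lengths[copies$replicon[copies$wraps]]
  }
  gr <- GenomicRanges::GRanges(
    seqnames = copies$replicon,
    ranges = IRanges::IRanges(start = copies$start, end = end),
    strand = ifelse(copies$orientation == "Forward", "+", "-")
  )
  S4Vectors::mcols(gr)$name <- copies$is_id
  S4Vectors::mcols(gr)$score <- round(copies$identity * 1000)
  gr
}

#' Write detected copies as BED6
#'
#' One feature per copy: name = variant label, score = identity x 1000.
#'
#' @param copies `is_copies` tibble.
#' @param path output file.
#' @param replicon_lengths named integer vector (required when any copy
#'   wraps the origin; such copies are clamped to the replicon end).
#' @export
write_copies_bed <- function(copies, path, replicon_lengths = NULL) {
  rtracklayer::export(copies_granges(copies, replicon_lengths), path,
                      format = "BED")
  invisible(path)
}

#' Write detected copies as GFF3 mobile_element features
#'
#' @param copies `is_copies` tibble.
#' @param path output file.
#' @param contexts optional [classify_contexts()] output; context codes
#'   are attached as a `context` attribute.
#' @param replicon_lengths see [write_copies_bed()].
#' @export
write_copies_gff3 <- function(copies, path, contexts = NULL,
                              replicon_lengths = NULL) {
  gr <- copies_granges(copies, replicon_lengths)
  S4Vectors::mcols(gr)$type <- "mobile_element"
  S4Vectors::mcols(gr)$ID <- copies$copy_id
  S4Vectors::mcols(gr)$identity <- sprintf("%.4f", copies$identity)
  if (!is.null(contexts)) {
    S4Vectors::mcols(gr)$context <-
      contexts$context_code[match(copies$copy_id, contexts$id)]
  }
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read a GFF3 annotation into the feature tibble used by
#' [classify_context()]
#'
#' @param path GFF3 file.
#' @param types feature types to keep (default CDS and ncRNA).
#' @return tibble: feature_id, start, end, strand, type, product.
#' @export
read_annotation_gff3 <- function(path, types = c("CDS", "ncRNA")) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[as.character(S4Vectors::mcols(gr)$type) %in% types]
  mc <- S4Vectors::mcols(gr)
  tibble::tibble(
    feature_id = if ("ID" %in% names(mc)) as.character(mc$ID)
                 else sprintf("feat_%04d", seq_along(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(mc$type),
    product = if ("product" %in% names(mc)) as.character(mc$product)
              else NA_character_
  )
}

#' Write an annotation tibble as GFF3
#'
#' @param features tibble with feature_id, start, end, strand, type,
#'   product.
#' @param path output file.
#' @param seqid sequence name for column 1.
#' @export
write_annotation_gff3 <- function(features, path, seqid = "seq") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand
  )
  S4Vectors::mcols(gr)$type <- features$type
  S4Vectors::mcols(gr)$ID <- features$feature_id
  S4Vectors::mcols(gr)$product <- features$product
  # whole-gene CDS features: phase 0 by construction
  S4Vectors::mcols(gr)$phase <- ifelse(features$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
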