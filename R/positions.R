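#' Merge overlapping alignments into distinct positions
#'
#' Collapses deduplicated, filtered alignments into *positions*: maximal
#' unions of transitively overlapping alignment intervals on the same
#' reference sequence, strand ignored. Positions are the unit of all
#' downstream density statistics. Overlap means shared bases: book-ended
#' intervals (`[0,50)`, `[50,80)`) are kept separate unless
#' `merge_adjacent = TRUE`.
#'
#' @param alignments Alignment data.frame with `reference_id`, `start`, `end`
#'   (0-based half-open).
#' @param merge_adjacent Also merge intervals that touch without overlapping.
#' @return A data.frame of class `chromseq_positions`: `reference_id`,
#'   `start`, `end` (0-based half-open), `n_reads` (number of constituent
#'   alignments), sorted by `(reference_id, start)`, pairwise disjoint within
#'   each reference.
#' @examples
#' aln <- data.frame(reference_id = "chrA", start = c(0, 40, 100),
#'                   end = c(50, 90, 120))
#' merge_positions(aln)
#' @export
merge_positions <- function(alignments, merge_adjacent = FALSE) {
  empty <- data.frame(reference_id = character(), start = numeric(),
                      end = numeric(), n_reads = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("chromseq_positions", "data.frame")
  if (nrow(alignments) == 0L) return(empty)
  gr <- GenomicRanges::GRanges(
    alignments$reference_id,
    IRanges::IRanges(start = alignments$start + 1, end = alignments$end))
  merged <- GenomicRanges::reduce(
    gr, min.gapwidth = if (merge_adjacent) 1L else 0L)
  n_reads <- GenomicRanges::countOverlaps(merged, gr,
                                          type = "any", minoverlap = 1L)
  out <- data.frame(
    reference_id = as.character(GenomicAlignments::seqnames(merged)),
    start = IRanges::start(merged) - 1,
    end = as.numeric(IRanges::end(merged)),
    n_reads = as.integer(n_reads),
    stringsAsFactors = FALSE)
  out <- out[radix_order(out$reference_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("chromseq_positions", "data.frame")
  out
}

#' Write positions or regions to BED
#'
#' BED is 0-based half-open, matching the package's internal convention, so
#' coordinates are written as they are. For positions the score column is
#' `n_reads`; for regions it is `n_positions`.
#'
#' @param x A positions or regions data.frame.
#' @param path Output `.bed` path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  score <- if ("n_reads" %in% names(x)) x$n_reads
           else if ("n_positions" %in% names(x)) x$n_positions
           else rep(0L, nrow(x))
  name <- if ("label" %in% names(x)) x$label
          else sprintf("p%06d", seq_len(nrow(x)))
  tab <- data.frame(x$reference_id, format(x$start, scientific = FALSE,
                                           trim = TRUE),
                    format(x$end, scientific = FALSE, trim = TRUE),
                    name, score, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
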