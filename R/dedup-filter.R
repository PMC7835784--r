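#' Alignment filter configuration
#'
#' Thresholds applied after duplicate removal: minimum mapping quality and
#' minimum aligned query length, both inclusive. Defaults are the
#' conventional "MAPQ 20, alignment length 20" used for chromosome-specific
#' sequencing data.
#'
#' @param min_mapq Minimum MAPQ (inclusive). MAPQ 255 ("unavailable") always
#'   fails.
#' @param min_aligned_length Minimum aligned query length in bp (inclusive).
#' @return A list of class `chromseq_filter_config`.
#' @export
filter_config <- function(min_mapq = 20L, min_aligned_length = 20L) {
  structure(list(min_mapq = check_pos_int(min_mapq, "min_mapq", min = 0L),
                 min_aligned_length = check_pos_int(min_aligned_length,
                                                    "min_aligned_length",
                                                    min = 0L)),
            class = "chromseq_filter_config")
}

#' Remove PCR duplicates by mapping coordinate
#'
#' Picard-style coordinate deduplication: among alignments sharing
#' `(reference_id, start, strand)`, exactly one is retained — the one with the
#' highest MAPQ, ties broken by lexicographically smallest `query_id`. The
#' 5' mapping start plus strand is the duplicate key; sequence content is not
#' consulted.
#'
#' @param alignments Alignment data.frame sorted by `(reference_id, start)`
#'   (as produced by [read_alignments()]); unsorted input is an error.
#' @return A list with `alignments` (deduplicated, original sort order) and
#'   `removed_fraction` (fraction of input records removed; `NA` for empty
#'   input).
#' @export
deduplicate <- function(alignments) {
  a <- alignments
  n <- nrow(a)
  if (n == 0L) return(list(alignments = a, removed_fraction = NA_real_))
  if (dedup_is_unsorted(a))
    stop("deduplicate() requires input sorted by (reference_id, start)",
         call. = FALSE)
  key <- paste(a$reference_id, a$start, a$strand, sep = "\r")
  best <- radix_order(key, -a$mapq, a$query_id)
  keep_idx <- best[!duplicated(key[best])]
  keep <- sort(keep_idx)
  list(alignments = a[keep, , drop = FALSE],
       removed_fraction = (n - length(keep)) / n)
}

dedup_is_unsorted <- function(a) {
  grp <- cumsum(c(TRUE, a$reference_id[-1L] != a$reference_id[-nrow(a)]))
  if (anyDuplicated(a$reference_id[!duplicated(grp)]) > 0L) return(TRUE)
  d <- diff(a$start)
  any(d[grp[-1L] == grp[-nrow(a)]] < 0)
}

#' Apply MAPQ and aligned-length filters
#'
#' Retains alignments with `mapq >= min_mapq` **and**
#' `aligned_length >= min_aligned_length` (both inclusive). Records with
#' MAPQ 255, which the SAM specification defines as "mapping quality
#' unavailable", fail any threshold.
#'
#' @param alignments Alignment data.frame.
#' @param cfg A [filter_config()].
#' @return The retained alignments.
#' @export
filter_alignments <- function(alignments, cfg) {
  stopifnot(inherits(cfg, "chromseq_filter_config"))
  keep <- alignments$mapq >= cfg$min_mapq & alignments$mapq != 255L &
    alignments$aligned_length >= cfg$min_aligned_length
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean read-to-reference divergence
#'
#' The per-read mean of `edit_distance / aligned_length` (SNPs and indels
#' combined, from the `NM` tag), the usual summary of how far a
#' chromosome-specific library sits from its reference assembly.
#'
#' @param alignments Non-empty alignment data.frame.
#' @return A single fraction.
#' @export
divergence_summary <- function(alignments) {
  if (nrow(alignments) == 0L)
    stop("divergence is undefined for an empty alignment set", call. = FALSE)
  mean(alignments$edit_distance / alignments$aligned_length)
}
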