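#' Region-detection configuration
#'
#' Positions are chained into candidate regions by single-linkage distance
#' clustering: consecutive positions on a reference stay in one chain while
#' the start-to-start gap is at most `max_gap`. `max_gap = "auto"` sets the
#' threshold to a fraction of the expected genome-wide position spacing,
#' `(total reference length / total positions) / auto_gap_divisor` —
#' appropriate when on-target positions dominate the genome-wide average
#' spacing only mildly, as on a genome-scale reference. The numeric default
#' (1700 bp) is sized for the package's default simulated conditions, sitting
#' roughly an order of magnitude above the expected dense-region position
#' spacing and well below the background spacing; see the methods vignette
#' for the derivation.
#'
#' @param max_gap Maximum start-to-start gap in bp, or `"auto"`.
#' @param min_region_positions Minimum positions per reported region
#'   (default 15, the same count used for scaffold assignment).
#' @param auto_gap_divisor Divisor for the `"auto"` rule (default 4).
#' @return A list of class `chromseq_region_config`.
#' @export
region_config <- function(max_gap = 1700, min_region_positions = 15L,
                          auto_gap_divisor = 4) {
  if (!(identical(max_gap, "auto") ||
        (is.numeric(max_gap) && length(max_gap) == 1L && max_gap > 0)))
    stop_config("max_gap", 'must be a positive number or "auto"')
  structure(list(max_gap = max_gap,
                 min_region_positions = check_pos_int(min_region_positions,
                                                      "min_region_positions",
                                                      min = 2L),
                 auto_gap_divisor = check_pos_num(auto_gap_divisor,
                                                  "auto_gap_divisor")),
            class = "chromseq_region_config")
}

#' Detect position-dense regions
#'
#' Chains positions per reference sequence while the start-to-start gap is at
#' most `max_gap`; chains with at least `min_region_positions` positions
#' become region calls. Each call spans first-position start to last-position
#' end and reports the position count, density (positions per kb), the pd
#' statistic (mean start-to-start gap within the region) and an exact
#' binomial enrichment p-value against a uniform background
#' (see [region_pvalue()]).
#'
#' @param positions Positions from [merge_positions()].
#' @param reference_lengths Named vector of reference sequence lengths (bp).
#' @param cfg A [region_config()].
#' @param genome_length Background genome size for the enrichment test;
#'   defaults to `sum(reference_lengths)`. Pass the non-N (mappable) total to
#'   exclude assembly gaps.
#' @return A data.frame of class `chromseq_regions`: `reference_id`, `start`,
#'   `end`, `n_positions`, `density`, `pd`, `p_value`, disjoint and sorted.
#'   An empty position set yields an empty result.
#' @export
detect_regions <- function(positions, reference_lengths, cfg = region_config(),
                           genome_length = sum(reference_lengths)) {
  stopifnot(inherits(cfg, "chromseq_region_config"))
  empty <- data.frame(reference_id = character(), start = numeric(),
                      end = numeric(), n_positions = integer(),
                      density = numeric(), pd = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("chromseq_regions", "data.frame")
  if (nrow(positions) == 0L) return(empty)

  n_total <- nrow(positions)
  max_gap <- if (identical(cfg$max_gap, "auto"))
    (sum(reference_lengths) / n_total) / cfg$auto_gap_divisor
  else cfg$max_gap

  out <- list()
  for (ref in unique(positions$reference_id)) {
    p <- positions[positions$reference_id == ref, , drop = FALSE]
    p <- p[radix_order(p$start), , drop = FALSE]
    gap <- diff(p$start)
    chain <- cumsum(c(1L, as.integer(gap > max_gap)))
    for (g in split(seq_len(nrow(p)), chain)) {
      if (length(g) < cfg$min_region_positions) next
      starts <- p$start[g]
      span_start <- starts[1L]
      span_end <- p$end[g[length(g)]]
      span <- span_end - span_start
      out[[length(out) + 1L]] <- data.frame(
        reference_id = ref, start = span_start, end = span_end,
        n_positions = length(g),
        density = length(g) / (span / 1000),
        pd = pd_statistic(starts),
        p_value = region_pvalue(length(g), n_total, span, genome_length),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[radix_order(res$reference_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "max_gap") <- max_gap
  class(res) <- c("chromseq_regions", "data.frame")
  res
}

#' Exact binomial enrichment p-value
#'
#' Under a uniform background, the number of positions falling in a span of
#' `span` bp out of `genome_length` is Binomial(`n_total`,
#' `span / genome_length`). Returns the upper tail `P(X >= k)` exactly.
#'
#' @param k Observed position count in the span.
#' @param n_total Total positions genome-wide.
#' @param span Span length in bp.
#' @param genome_length Background genome length in bp (`>= span`).
#' @return The enrichment probability.
#' @examples
#' region_pvalue(5, 100, 1, 100)   # span fraction 0.01
#' @export
region_pvalue <- function(k, n_total, span, genome_length) {
  if (span > genome_length)
    stop("region span exceeds genome length", call. = FALSE)
  if (n_total < k)
    stop("n_total must be at least the observed count", call. = FALSE)
  if (k <= 0) return(1)
  pbinom(k - 1, n_total, span / genome_length, lower.tail = FALSE)
}

#' Mean distance between consecutive positions
#'
#' The pd statistic: the mean start-to-start gap between consecutive sorted
#' positions on one reference sequence or within one region. Small pd means
#' dense coverage, i.e. chromosome membership or a candidate region.
#'
#' @param starts Numeric vector of at least two position starts (any order).
#' @return Mean gap in bp.
#' @examples
#' pd_statistic(c(100, 200, 400))  # 150
#' @export
pd_statistic <- function(starts) {
  if (length(starts) < 2L)
    stop("pd is undefined for fewer than two positions", call. = FALSE)
  mean(diff(sort(starts)))
}
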