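#' Scaffold-assignment configuration
#'
#' The decision rule for attributing a reference sequence to the sampled
#' chromosome: at least `min_positions` merged positions *and* enrichment
#' p-value below `alpha`. Defaults are the stringent published criteria
#' (15 positions, p < 0.05) applied to raw p-values; Benjamini-Hochberg
#' adjustment is available behind `adjust`.
#'
#' @param min_positions Minimum merged positions (default 15).
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (raw p-values, the default) or `"BH"`.
#' @return A list of class `chromseq_assign_config`.
#' @export
assign_config <- function(min_positions = 15L, alpha = 0.05,
                          adjust = c("none", "BH")) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_config("alpha", "must be in (0, 1)")
  structure(list(min_positions = check_pos_int(min_positions, "min_positions"),
                 alpha = alpha, adjust = match.arg(adjust)),
            class = "chromseq_assign_config")
}

#' Score reference sequences for chromosome membership
#'
#' One record per reference sequence: observed merged-position count, the
#' count expected under a uniform background (`n_total * length /
#' genome_length`), the exact binomial upper-tail enrichment p-value, and the
#' pd statistic (NA with fewer than two positions). The background genome
#' length defaults to the non-N (mappable) total when provided, since reads
#' cannot map into assembly gaps and counting them would inflate
#' significance.
#'
#' @param positions Positions from [merge_positions()]. Every
#'   `reference_id` present must appear in `reference_lengths`.
#' @param reference_lengths Named vector of reference sequence lengths (bp).
#' @param mappable_lengths Optional named vector of non-N lengths; defaults
#'   to `reference_lengths`.
#' @return A data.frame of class `chromseq_scores`: `reference_id`, `length`,
#'   `n_positions`, `expected`, `p_value`, `pd`.
#' @export
score_scaffolds <- function(positions, reference_lengths,
                            mappable_lengths = reference_lengths) {
  unknown <- setdiff(unique(positions$reference_id), names(reference_lengths))
  if (length(unknown) > 0L)
    stop(sprintf("positions on reference id(s) absent from lengths: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  stopifnot(identical(names(reference_lengths), names(mappable_lengths)))

  ids <- names(reference_lengths)
  n_total <- nrow(positions)
  genome_length <- sum(mappable_lengths)
  counts <- table(factor(positions$reference_id, levels = ids))
  pd <- vapply(ids, function(id) {
    s <- positions$start[positions$reference_id == id]
    if (length(s) < 2L) NA_real_ else pd_statistic(s)
  }, numeric(1))

  out <- data.frame(
    reference_id = ids,
    length = as.numeric(reference_lengths),
    n_positions = as.integer(counts),
    expected = n_total * as.numeric(mappable_lengths) / genome_length,
    p_value = vapply(seq_along(ids), function(i)
      region_pvalue(as.integer(counts[i]), n_total,
                    as.numeric(mappable_lengths[i]), genome_length),
      numeric(1)),
    pd = unname(pd),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("chromseq_scores", "data.frame")
  out
}

#' Assign scaffolds to the sampled chromosome
#'
#' Applies the conjunction rule to scored reference sequences: assigned iff
#' `n_positions >= min_positions` **and** (possibly adjusted) `p_value <
#' alpha`. The decision is order-invariant.
#'
#' @param scores Output of [score_scaffolds()].
#' @param cfg An [assign_config()].
#' @param scaffold_pattern Optional regular expression; when given, the
#'   assigned set and total are restricted to reference ids matching it
#'   (typically the unplaced-scaffold naming scheme), so assembled
#'   chromosomes are not re-assigned to themselves.
#' @return A list with `table` (scores plus `p_adjusted` and logical
#'   `assigned`), `assigned` (the assigned subset), and `assigned_bp` (total
#'   length of assigned sequences).
#' @export
assign_scaffolds <- function(scores, cfg = assign_config(),
                             scaffold_pattern = NULL) {
  stopifnot(inherits(cfg, "chromseq_assign_config"))
  tab <- as.data.frame(scores)
  eligible <- if (is.null(scaffold_pattern)) rep(TRUE, nrow(tab))
              else grepl(scaffold_pattern, tab$reference_id)
  tab$p_adjusted <- tab$p_value
  if (cfg$adjust == "BH" && any(eligible))
    tab$p_adjusted[eligible] <- p.adjust(tab$p_value[eligible], method = "BH")
  tab$assigned <- eligible & tab$n_positions >= cfg$min_positions &
    tab$p_adjusted < cfg$alpha
  assigned <- tab[tab$assigned, , drop = FALSE]
  rownames(assigned) <- NULL
  list(table = tab, assigned = assigned,
       assigned_bp = sum(assigned$length))
}

#' Write an AGP placing assigned scaffolds on a chromosome
#'
#' Emits an AGP v2.1 object that concatenates the assigned scaffolds
#' (unordered and unoriented: orientation `na`), separated by 100 bp `U`
#' gaps, onto a named chromosome object. Chromosome-specific read data alone
#' cannot order or orient scaffolds, so this is an explicit "bag of
#' scaffolds" model.
#'
#' @param assigned The `assigned` table from [assign_scaffolds()].
#' @param chromosome_name Object name for the assembled chromosome.
#' @param path Output `.agp` path.
#' @return `path`, invisibly.
#' @export
write_assigned_agp <- function(assigned, chromosome_name, path) {
  rows <- list()
  pos <- 0
  part <- 0L
  for (i in seq_len(nrow(assigned))) {
    if (i > 1L) {
      part <- part + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        object = chromosome_name, object_beg = pos + 1, object_end = pos + 100,
        part_number = part, component_type = "U", col6 = "100",
        col7 = "scaffold", col8 = "no", col9 = "na", stringsAsFactors = FALSE)
      pos <- pos + 100
    }
    part <- part + 1L
    len <- assigned$length[i]
    rows[[length(rows) + 1L]] <- data.frame(
      object = chromosome_name, object_beg = pos + 1, object_end = pos + len,
      part_number = part, component_type = "W",
      col6 = assigned$reference_id[i], col7 = "1",
      col8 = format(len, scientific = FALSE, trim = TRUE), col9 = "na",
      stringsAsFactors = FALSE)
    pos <- pos + len
  }
  agp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(object = character(), object_beg = integer(),
               object_end = integer(), part_number = integer(),
               component_type = character(), col6 = character(),
               col7 = character(), col8 = character(), col9 = character())
  write_agp(agp, path)
}
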