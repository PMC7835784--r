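#' Contig track from a reference FASTA
#'
#' Contigs are maximal runs of non-N bases. Runs of N shorter than
#' `min_gap_length` are kept inside a contig (they are ambiguous bases, not
#' assembly gaps); runs at least that long separate contigs. An empty
#' sequence contributes no contigs.
#'
#' @param reference Path to a FASTA file, or a `Biostrings::DNAStringSet`.
#' @param min_gap_length Minimum N-run length treated as a gap (default 10).
#' @return A data.frame of class `chromseq_contig_track`: `reference_id`,
#'   `start`, `end` (0-based half-open), sorted and non-overlapping, with the
#'   reference lengths as attribute `reference_lengths`.
#' @export
contig_track_from_fasta <- function(reference, min_gap_length = 10L) {
  seqs <- if (methods::is(reference, "DNAStringSet")) reference
          else Biostrings::readDNAStringSet(reference)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  rows <- list()
  for (id in names(seqs)) {
    x <- seqs[[id]]
    if (length(x) == 0L) next
    nruns <- IRanges::reduce(as(Biostrings::matchPattern("N", x), "IRanges"))
    nruns <- nruns[IRanges::width(nruns) >= min_gap_length]
    contigs <- IRanges::setdiff(IRanges::IRanges(1L, length(x)), nruns)
    if (length(contigs) == 0L) next
    rows[[id]] <- data.frame(reference_id = id,
                             start = IRanges::start(contigs) - 1,
                             end = as.numeric(IRanges::end(contigs)),
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reference_id = character(), start = numeric(),
               end = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "reference_lengths") <- setNames(as.numeric(Biostrings::width(seqs)),
                                             names(seqs))
  class(out) <- c("chromseq_contig_track", "data.frame")
  out
}

#' Contig track from an AGP file
#'
#' `W` component lines become contig intervals (object coordinates converted
#' to 0-based half-open); `N`/`U` lines are gaps. Overlapping components
#' within an object are a format error.
#'
#' @param agp Path to an AGP v2.1 file, or a data.frame from [read_agp()].
#' @return A `chromseq_contig_track` data.frame (see
#'   [contig_track_from_fasta()]); reference lengths are taken as the largest
#'   object coordinate per object.
#' @export
contig_track_from_agp <- function(agp) {
  tab <- if (is.character(agp)) read_agp(agp) else agp
  w <- tab[tab$component_type == "W", , drop = FALSE]
  out <- data.frame(reference_id = w$object, start = w$object_beg - 1,
                    end = as.numeric(w$object_end), stringsAsFactors = FALSE)
  out <- out[radix_order(out$reference_id, out$start), , drop = FALSE]
  for (id in unique(out$reference_id)) {
    o <- out[out$reference_id == id, , drop = FALSE]
    if (nrow(o) > 1L && any(o$start[-1L] < o$end[-nrow(o)]))
      stop(sprintf("AGP format error: overlapping components on object %s", id),
           call. = FALSE)
  }
  rownames(out) <- NULL
  lens <- tapply(tab$object_end, tab$object, max)
  attr(out, "reference_lengths") <- setNames(as.numeric(lens), names(lens))
  class(out) <- c("chromseq_contig_track", "data.frame")
  out
}

#' Classify a detected region by contig-boundary correspondence
#'
#' A dense off-target region whose margins coincide with contig ends points to
#' an assembly join error (the contigs between the gaps belong elsewhere),
#' whereas a region strictly inside contiguous sequence is better explained as
#' a real translocation in the sampled genome. The rule: both region margins
#' within `tolerance` of a contig boundary yields `assembly_discordant`;
#' neither margin close to a boundary yields `putative_translocation`;
#' exactly one yields `indeterminate`. The labels are exhaustive and mutually
#' exclusive, and growing `tolerance` can only move a label toward
#' `assembly_discordant` (through `indeterminate`), never away.
#'
#' @param region One row of a [detect_regions()] result (or any list/row with
#'   `reference_id`, `start`, `end`).
#' @param track A contig track containing `region$reference_id`.
#' @param tolerance Margin tolerance in bp; a sensible choice is the region
#'   detection `max_gap`, since detected margins cannot be located more
#'   precisely than the chaining distance.
#' @return One of `"assembly_discordant"`, `"putative_translocation"`,
#'   `"indeterminate"`.
#' @export
classify_region <- function(region, track, tolerance) {
  contigs <- track[track$reference_id == region$reference_id, , drop = FALSE]
  if (nrow(contigs) == 0L)
    stop(sprintf("reference %s not present in contig track",
                 region$reference_id), call. = FALSE)
  boundaries <- sort(unique(c(contigs$start, contigs$end)))
  near <- function(x) min(abs(boundaries - x)) <= tolerance
  hits <- near(region$start) + near(region$end)
  c("putative_translocation", "indeterminate",
    "assembly_discordant")[hits + 1L]
}

#' Overlap of regions with an external homology track
#'
#' Reporting hook for cross-species homology evidence: given a BED file of
#' homology blocks (e.g. alignments to another species' chromosomes), reports
#' the fraction of each region covered by each homology name. The package
#' reports these fractions without interpreting them; corroborating a
#' misassembly call with discordant cross-species homology is left to the
#' analyst.
#'
#' @param regions A [detect_regions()] result.
#' @param bed_path BED file of homology blocks; the BED name column labels
#'   the homologous chromosome.
#' @return A data.frame `reference_id`, `start`, `end`, `homology`,
#'   `overlap_fraction`, one row per region x homology label with non-zero
#'   overlap.
#' @export
region_homology_overlap <- function(regions, bed_path) {
  hom <- rtracklayer::import(bed_path, format = "BED")
  out <- list()
  for (i in seq_len(nrow(regions))) {
    r <- GenomicRanges::GRanges(regions$reference_id[i],
                                IRanges::IRanges(regions$start[i] + 1,
                                                 regions$end[i]))
    hits <- IRanges::subsetByOverlaps(hom, r)
    if (length(hits) == 0L) next
    ov <- IRanges::pintersect(rep(r, length(hits)),
                              GenomicRanges::granges(hits))
    frac <- tapply(IRanges::width(ov), hits$name, sum) /
      (regions$end[i] - regions$start[i])
    out[[length(out) + 1L]] <- data.frame(
      reference_id = regions$reference_id[i], start = regions$start[i],
      end = regions$end[i], homology = names(frac),
      overlap_fraction = as.numeric(frac), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(reference_id = character(), start = numeric(),
                      end = numeric(), homology = character(),
                      overlap_fraction = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
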