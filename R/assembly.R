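#' Build a simulated reference assembly with ground truth
#'
#' Generates a multi-chromosome assembly with unplaced scaffolds, splits
#' chromosomes into contigs separated by N gaps, and (optionally) plants a
#' misassembled segment: a block of target-chromosome material placed inside a
#' different ("host") chromosome, with both margins coinciding exactly with
#' contig boundaries — the signature used downstream to call an assembly
#' discordance. The planted segment is synthesised as unique target-labelled
#' sequence present only at its (wrong) assembled location, as a real
#' misassembly would be.
#'
#' Deterministic given `cfg$seed`: the same configuration always yields
#' byte-identical outputs.
#'
#' @param cfg A [sim_config()] object.
#' @param outdir Optional directory; when given, writes `genome.fa`
#'   (reference FASTA), `genome.agp` (AGP v2.1 contig map) and `truth.tsv`
#'   (reference id, true membership, misassembled-region coordinates).
#' @return An object of class `chromseq_truth`: a list with
#'   \describe{
#'     \item{sequences}{`DNAStringSet` of chromosomes and scaffolds.}
#'     \item{contig_map}{data.frame `reference_id`, `start`, `end`
#'       (0-based half-open contig intervals).}
#'     \item{membership}{data.frame `reference_id`, `membership`
#'       (`"target"`, `"other"`, or a chromosome id).}
#'     \item{misassembled_regions}{data.frame `reference_id`, `start`, `end`
#'       of planted regions truly deriving from the target chromosome.}
#'   }
#' @examples
#' cfg <- sim_config(n_reads = 200, chromosome_lengths = c(2e5, 1e5, 1e5),
#'                   misassembly = NULL, n_unplaced_scaffolds = 2,
#'                   n_target_scaffolds = 1,
#'                   scaffold_length_range = c(2e4, 4e4),
#'                   contig_length_range = c(2e4, 5e4))
#' truth <- build_assembly(cfg)
#' names(truth$sequences)
#' @export
build_assembly <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "chromseq_sim_config"))
  set.seed(cfg$seed)

  chrom_ids <- paste0("chr", seq_len(cfg$n_chromosomes))
  mis <- cfg$misassembly

  seqs <- character(0)
  contig_map <- list()
  mis_regions <- data.frame(reference_id = character(), start = numeric(),
                            end = numeric(), stringsAsFactors = FALSE)

  for (i in seq_len(cfg$n_chromosomes)) {
    id <- chrom_ids[i]
    L <- cfg$chromosome_lengths[i]
    if (!is.null(mis) && identical(mis$host_chromosome, id)) {
      built <- build_host_chromosome(L, mis, cfg)
      mis_regions <- rbind(mis_regions, data.frame(
        reference_id = id, start = mis$insert_position,
        end = mis$insert_position + mis$insert_length,
        stringsAsFactors = FALSE))
    } else {
      built <- build_plain_sequence(L, cfg)
    }
    seqs[id] <- built$seq
    contig_map[[id]] <- data.frame(reference_id = id,
                                   start = built$contigs$start,
                                   end = built$contigs$end,
                                   stringsAsFactors = FALSE)
  }

  n_scaf <- cfg$n_unplaced_scaffolds
  scaffold_ids <- character(0)
  if (n_scaf > 0L) {
    scaffold_ids <- sprintf("scaffold_%03d", seq_len(n_scaf))
    scaf_len <- floor(runif(n_scaf, cfg$scaffold_length_range[1],
                            cfg$scaffold_length_range[2] + 1))
    for (j in seq_len(n_scaf)) {
      id <- scaffold_ids[j]
      seqs[id] <- random_dna(scaf_len[j])
      contig_map[[id]] <- data.frame(reference_id = id, start = 0,
                                     end = scaf_len[j], stringsAsFactors = FALSE)
    }
  }
  target_scaf <- if (n_scaf > 0L)
    sort(sample.int(n_scaf, cfg$n_target_scaffolds)) else integer(0)

  membership <- data.frame(
    reference_id = c(chrom_ids, scaffold_ids),
    membership = c(ifelse(chrom_ids == cfg$target_chromosome, "target",
                          chrom_ids),
                   ifelse(seq_len(n_scaf) %in% target_scaf, "target", "other")),
    stringsAsFactors = FALSE)

  truth <- structure(list(sequences = Biostrings::DNAStringSet(seqs),
                          contig_map = do.call(rbind, unname(contig_map)),
                          membership = membership,
                          misassembled_regions = mis_regions,
                          config = cfg),
                     class = "chromseq_truth")
  rownames(truth$contig_map) <- NULL
  if (!is.null(outdir)) write_assembly(truth, outdir)
  truth
}

# Tile [offset, offset+len) with contigs separated by N gaps; the tiling ends
# exactly at offset+len with a contig (no trailing gap).
tile_contigs <- function(offset, len, cfg) {
  cmin <- cfg$contig_length_range[1]
  cmax <- cfg$contig_length_range[2]
  gap <- cfg$gap_length
  starts <- numeric(0)
  ends <- numeric(0)
  pos <- offset
  remaining <- len
  while (remaining > 0) {
    if (remaining <= cmax + gap + cmin) {
      starts <- c(starts, pos); ends <- c(ends, pos + remaining)
      remaining <- 0
    } else {
      w <- floor(runif(1, cmin, cmax + 1))
      starts <- c(starts, pos); ends <- c(ends, pos + w)
      pos <- pos + w + gap
      remaining <- remaining - w - gap
    }
  }
  data.frame(start = starts, end = ends)
}

# Sequence string from a contig layout: contigs random DNA, gaps N runs.
realize_sequence <- function(contigs, total_len) {
  pieces <- character(0)
  prev <- 0
  for (i in seq_len(nrow(contigs))) {
    if (contigs$start[i] > prev)
      pieces <- c(pieces, strrep("N", contigs$start[i] - prev))
    pieces <- c(pieces, random_dna(contigs$end[i] - contigs$start[i]))
    prev <- contigs$end[i]
  }
  if (total_len > prev) pieces <- c(pieces, strrep("N", total_len - prev))
  paste(pieces, collapse = "")
}

build_plain_sequence <- function(L, cfg) {
  contigs <- tile_contigs(0, L, cfg)
  list(seq = realize_sequence(contigs, L), contigs = contigs)
}

# Host chromosome carrying the planted misassembled segment. The segment
# occupies [insert_position, insert_position + insert_length) exactly; an N
# gap is carved out of the flanks immediately before and after it so that both
# margins are contig boundaries in the realized sequence as well as in the map.
build_host_chromosome <- function(L, mis, cfg) {
  gap <- cfg$gap_length
  ipos <- mis$insert_position
  iend <- mis$insert_position + mis$insert_length
  if (ipos < gap + cfg$contig_length_range[1] ||
      L - iend < gap + cfg$contig_length_range[1])
    stop_config("misassembly",
                "insert must leave room for flanking contigs and gaps")
  left <- tile_contigs(0, ipos - gap, cfg)
  insert <- tile_contigs(ipos, mis$insert_length, cfg)
  right <- tile_contigs(iend + gap, L - iend - gap, cfg)
  contigs <- rbind(left, insert, right)
  list(seq = realize_sequence(contigs, L), contigs = contigs)
}

#' Write a simulated assembly to disk
#'
#' Writes `genome.fa`, `genome.agp` (AGP v2.1: `W` components for contigs,
#' `N` gap lines) and `truth.tsv` (one row per reference sequence:
#' `reference_id`, `membership`, `region_start`, `region_end`, the last two
#' `NA` unless the sequence hosts a planted misassembled region).
#'
#' @param truth A `chromseq_truth` object from [build_assembly()].
#' @param outdir Output directory (created if missing).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_assembly <- function(truth, outdir) {
  stopifnot(inherits(truth, "chromseq_truth"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(outdir, "genome.fa")
  agp <- file.path(outdir, "genome.agp")
  tsv <- file.path(outdir, "truth.tsv")

  Biostrings::writeXStringSet(truth$sequences, fa)

  ids <- names(truth$sequences)
  rows <- lapply(ids, function(id) {
    contigs <- truth$contig_map[truth$contig_map$reference_id == id, ,
                                drop = FALSE]
    agp_rows_for_object(id, contigs,
                        sprintf("%s_ctg%03d", id, seq_len(nrow(contigs))))
  })
  write_agp(do.call(rbind, rows), agp)

  mem <- truth$membership
  mr <- truth$misassembled_regions
  idx <- match(mem$reference_id, mr$reference_id)
  tab <- data.frame(reference_id = mem$reference_id,
                    membership = mem$membership,
                    region_start = mr$start[idx],
                    region_end = mr$end[idx],
                    stringsAsFactors = FALSE)
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(c(fasta = fa, agp = agp, truth = tsv))
}

#' @export
print.chromseq_truth <- function(x, ...) {
  w <- Biostrings::width(x$sequences)
  cat(sprintf("chromseq simulated assembly: %d sequences, %s bp total\n",
              length(x$sequences), format(sum(w), big.mark = ",")))
  cat(sprintf("  %d contigs; %d misassembled region(s)\n",
              nrow(x$contig_map), nrow(x$misassembled_regions)))
  tgt <- x$membership$reference_id[x$membership$membership == "target"]
  cat(sprintf("  target material: %s%s\n",
              paste(utils::head(tgt, 5), collapse = ", "),
              if (length(tgt) > 5) sprintf(" and %d more", length(tgt) - 5) else ""))
  invisible(x)
}
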