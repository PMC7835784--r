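#' Configuration for the isolated-chromosome read simulator
#'
#' Builds and validates the configuration driving [build_assembly()] and
#' [simulate_reads()]. The defaults describe the simulated study conditions
#' used throughout the package's tests: a three-chromosome reference with 84
#' unplaced scaffolds of which 34 truly belong to the sampled ("target")
#' chromosome, one 1 Mb segment of target material misplaced inside another
#' chromosome, 80% chromosome-isolation purity, 70% PCR duplicates, and 2%
#' read-to-reference divergence, mirroring the published chromosome-6
#' reanalysis this pipeline reproduces at desk scale.
#'
#' @param seed Integer seed; all simulator randomness derives from it.
#' @param n_chromosomes Number of assembled chromosomes.
#' @param chromosome_lengths Integer vector of chromosome lengths in bp
#'   (length `n_chromosomes`). Names `chr1..chrN` are assigned in order.
#' @param n_unplaced_scaffolds Number of unplaced scaffolds in the assembly.
#' @param scaffold_length_range Length 2 vector, min/max scaffold length (bp).
#' @param n_target_scaffolds How many unplaced scaffolds truly derive from the
#'   target chromosome (the rest are decoys from elsewhere in the genome).
#' @param target_chromosome Reference id of the sampled chromosome.
#' @param misassembly `NULL`, or a list with `host_chromosome`,
#'   `insert_length` and `insert_position`: a segment of target-chromosome
#'   material placed inside another chromosome, with both margins forced onto
#'   contig boundaries.
#' @param purity Fraction of reads drawn from target material (target
#'   chromosome + target scaffolds + misassembled segment); the rest are
#'   background drawn uniformly from the whole assembly, emulating
#'   chromosome-isolation impurity.
#' @param duplicate_rate Fraction of reads that are coordinate-identical PCR
#'   duplicates of earlier reads (sequence and source interval copied
#'   verbatim).
#' @param error_rate Per-base substitution+indel rate.
#' @param read_length Read length in bp (before any primer tail).
#' @param n_reads Total number of reads to emit.
#' @param primer IUPAC string prepended (5') to a fraction of reads; default
#'   is the degenerate DOP-PCR primer 5'-CCGACTCGAGNNNNNNATGTGG-3'.
#' @param primer_fraction Fraction of reads carrying the primer tail.
#' @param contig_length_range Min/max contig length (bp) used when splitting
#'   chromosomes into contigs separated by N gaps.
#' @param gap_length Length of the N gap between consecutive contigs (bp).
#' @param low_mapq_fraction Fraction of background reads given MAPQ < 20 in
#'   the truth alignments, to exercise the mapping-quality filter. Reads from
#'   unique target material always get MAPQ 60.
#' @return A validated list of class `chromseq_sim_config`.
#' @examples
#' cfg <- sim_config(n_reads = 500, chromosome_lengths = c(2e5, 1e5, 1e5),
#'                   misassembly = NULL, n_unplaced_scaffolds = 4,
#'                   n_target_scaffolds = 2,
#'                   scaffold_length_range = c(2e4, 4e4),
#'                   contig_length_range = c(2e4, 5e4))
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       chromosome_lengths = c(30e6, 16e6, 1e6),
                       n_unplaced_scaffolds = 84L,
                       scaffold_length_range = c(1e4, 2.5e4),
                       n_target_scaffolds = 34L,
                       target_chromosome = "chr3",
                       misassembly = list(host_chromosome = "chr1",
                                          insert_length = 1e6,
                                          insert_position = 14e6),
                       purity = 0.8,
                       duplicate_rate = 0.7,
                       error_rate = 0.02,
                       read_length = 100L,
                       n_reads = 1e5,
                       primer = "CCGACTCGAGNNNNNNATGTGG",
                       primer_fraction = 0.5,
                       contig_length_range = c(5e4, 5e5),
                       gap_length = 100L,
                       low_mapq_fraction = 0.1) {
  cfg <- list(seed = check_pos_int(seed, "seed", min = 0L),
              n_chromosomes = check_pos_int(n_chromosomes, "n_chromosomes"),
              chromosome_lengths = chromosome_lengths,
              n_unplaced_scaffolds = check_pos_int(n_unplaced_scaffolds,
                                                   "n_unplaced_scaffolds",
                                                   min = 0L),
              scaffold_length_range = scaffold_length_range,
              n_target_scaffolds = check_pos_int(n_target_scaffolds,
                                                 "n_target_scaffolds", min = 0L),
              target_chromosome = target_chromosome,
              misassembly = misassembly,
              purity = check_fraction(purity, "purity"),
              duplicate_rate = check_fraction(duplicate_rate, "duplicate_rate"),
              error_rate = check_fraction(error_rate, "error_rate"),
              read_length = check_pos_int(read_length, "read_length"),
              n_reads = check_pos_int(n_reads, "n_reads"),
              primer = primer,
              primer_fraction = check_fraction(primer_fraction, "primer_fraction"),
              contig_length_range = contig_length_range,
              gap_length = check_pos_int(gap_length, "gap_length"),
              low_mapq_fraction = check_fraction(low_mapq_fraction,
                                                 "low_mapq_fraction"))

  if (!is.numeric(chromosome_lengths) ||
      length(chromosome_lengths) != cfg$n_chromosomes ||
      any(chromosome_lengths <= 0))
    stop_config("chromosome_lengths",
                "must be positive and of length n_chromosomes")
  cfg$chromosome_lengths <- as.numeric(chromosome_lengths)

  for (fld in c("scaffold_length_range", "contig_length_range")) {
    r <- cfg[[fld]]
    if (!is.numeric(r) || length(r) != 2L || any(r <= 0) || r[1L] > r[2L])
      stop_config(fld, "must be (min, max) with 0 < min <= max")
    cfg[[fld]] <- as.numeric(r)
  }

  if (cfg$n_target_scaffolds > cfg$n_unplaced_scaffolds)
    stop_config("n_target_scaffolds", "must be <= n_unplaced_scaffolds")

  chrom_ids <- paste0("chr", seq_len(cfg$n_chromosomes))
  if (!is.character(target_chromosome) || length(target_chromosome) != 1L ||
      !(target_chromosome %in% chrom_ids))
    stop_config("target_chromosome", "must name one of the chromosomes")

  if (!is.null(misassembly)) {
    need <- c("host_chromosome", "insert_length", "insert_position")
    if (!is.list(misassembly) || !all(need %in% names(misassembly)))
      stop_config("misassembly",
                  "must have host_chromosome, insert_length, insert_position")
    if (!(misassembly$host_chromosome %in% chrom_ids) ||
        identical(misassembly$host_chromosome, target_chromosome))
      stop_config("misassembly", "host_chromosome must be a non-target chromosome")
    ilen <- check_pos_num(misassembly$insert_length, "misassembly")
    ipos <- check_pos_num(misassembly$insert_position, "misassembly")
    host_len <- cfg$chromosome_lengths[match(misassembly$host_chromosome,
                                             chrom_ids)]
    if (ipos + ilen > host_len)
      stop_config("misassembly",
                  "insert_position + insert_length must be <= host chromosome length")
    cfg$misassembly <- list(host_chromosome = misassembly$host_chromosome,
                            insert_length = as.numeric(ilen),
                            insert_position = as.numeric(ipos))
  }

  if (!is.character(primer) || length(primer) != 1L || !is_iupac(primer))
    stop_config("primer", "must be a non-empty IUPAC string")

  structure(cfg, class = "chromseq_sim_config")
}

#' @export
print.chromseq_sim_config <- function(x, ...) {
  cat("chromseq simulator configuration\n")
  cat(sprintf("  %d chromosome(s): %s bp; target %s\n", x$n_chromosomes,
              paste(format(x$chromosome_lengths, big.mark = ",", trim = TRUE),
                    collapse = ", "),
              x$target_chromosome))
  cat(sprintf("  %d unplaced scaffolds (%d target), %s-%s bp\n",
              x$n_unplaced_scaffolds, x$n_target_scaffolds,
              format(x$scaffold_length_range[1], big.mark = ","),
              format(x$scaffold_length_range[2], big.mark = ",")))
  if (!is.null(x$misassembly))
    cat(sprintf("  misassembly: %s bp of target material at %s:%s\n",
                format(x$misassembly$insert_length, big.mark = ","),
                x$misassembly$host_chromosome,
                format(x$misassembly$insert_position, big.mark = ",")))
  cat(sprintf("  %s reads of %d bp; purity %.2f, duplicates %.2f, errors %.3f\n",
              format(x$n_reads, big.mark = ","), x$read_length, x$purity,
              x$duplicate_rate, x$error_rate))
  invisible(x)
}
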