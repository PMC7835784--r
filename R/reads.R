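BASES <- c("A", "C", "G", "T")

#' Simulate chromosome-specific sequencing reads
#'
#' Samples reads with the statistical structure of a whole-genome-amplified,
#' flow-sorted/microdissected chromosome library: a fraction `purity` of reads
#' from target material (the target chromosome, the target scaffolds and any
#' planted misassembled segment, uniformly by mappable length), the remainder
#' uniformly from the whole assembly (isolation impurity); a fraction
#' `duplicate_rate` of reads that are verbatim PCR-duplicate copies of earlier
#' reads; per-base substitution/indel errors at `error_rate`; and a degenerate
#' primer tail prepended to a fraction of reads. Reads are only drawn from
#' contig (non-N) sequence.
#'
#' Every read's true source interval is retained, so the result can be written
#' both as FASTQ and as a coordinate-sorted "truth" SAM whose alignments are
#' exact: primer tails appear as soft clips, indels in the CIGAR, and the
#' `NM` tag counts substitutions plus inserted/deleted bases. Reads from
#' target material get MAPQ 60; a configurable fraction of background reads
#' get MAPQ < 20 to exercise the mapping-quality filter.
#'
#' @param truth A `chromseq_truth` assembly from [build_assembly()].
#' @param cfg The same [sim_config()] used to build the assembly.
#' @return An object of class `chromseq_reads`: a data.frame with one row per
#'   read (`query_id`, `reference_id`, `start`, `end` 0-based half-open,
#'   `strand`, `mapq`, `cigar`, `nm`, `aligned_length`, `seq_fastq`,
#'   `seq_sam`, `is_duplicate`, `from_target`), carrying the reference lengths
#'   as an attribute for [write_reads()].
#' @seealso [write_reads()], [read_alignments()]
#' @export
simulate_reads <- function(truth, cfg) {
  stopifnot(inherits(truth, "chromseq_truth"),
            inherits(cfg, "chromseq_sim_config"))
  set.seed(cfg$seed + 1L)
  L <- cfg$read_length

  contigs <- truth$contig_map
  cw <- contigs$end - contigs$start
  if (L > min(cw))
    stop(sprintf("read_length (%d) longer than shortest contig (%d)",
                 L, as.integer(min(cw))), call. = FALSE)
  weight <- pmax(cw - L + 1, 0)

  target_refs <- truth$membership$reference_id[
    truth$membership$membership == "target"]
  in_target <- contigs$reference_id %in% target_refs
  mr <- truth$misassembled_regions
  for (k in seq_len(nrow(mr))) {
    in_target <- in_target | (contigs$reference_id == mr$reference_id[k] &
                              contigs$start >= mr$start[k] &
                              contigs$end <= mr$end[k])
  }
  if (!any(in_target & weight > 0))
    stop("no target contig long enough to sample reads from", call. = FALSE)

  n <- cfg$n_reads
  n_dup <- rbinom(1L, n, cfg$duplicate_rate)
  if (n_dup >= n) n_dup <- n - 1L
  n_u <- n - n_dup

  from_target <- runif(n_u) < cfg$purity
  ci <- integer(n_u)
  pool_t <- which(in_target & weight > 0)
  pool_a <- which(weight > 0)
  ci[from_target] <- pool_t[sample.int(length(pool_t), sum(from_target),
                                       replace = TRUE, prob = weight[pool_t])]
  ci[!from_target] <- pool_a[sample.int(length(pool_a), sum(!from_target),
                                        replace = TRUE, prob = weight[pool_a])]
  start <- contigs$start[ci] + floor(runif(n_u) * weight[ci])
  refid <- contigs$reference_id[ci]
  strand <- ifelse(runif(n_u) < 0.5, "+", "-")

  seq_chars <- as.character(truth$sequences)
  span <- character(n_u)
  for (id in unique(refid)) {
    sel <- refid == id
    span[sel] <- substring(seq_chars[[id]], start[sel] + 1, start[sel] + L)
  }

  err <- inject_errors(span, L, cfg$error_rate)

  core_fastq <- err$read
  rc_sel <- strand == "-"
  if (any(rc_sel))
    core_fastq[rc_sel] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(err$read[rc_sel])))

  has_primer <- runif(n_u) < cfg$primer_fraction
  np <- nchar(cfg$primer)
  primer_inst <- character(n_u)
  primer_inst[has_primer] <- instantiate_primer(cfg$primer, sum(has_primer))

  seq_fastq <- paste0(primer_inst, core_fastq)
  cigar <- err$cigar
  seq_sam <- err$read
  pp <- has_primer & !rc_sel
  pm <- has_primer & rc_sel
  if (any(pp)) {
    seq_sam[pp] <- paste0(primer_inst[pp], err$read[pp])
    cigar[pp] <- paste0(np, "S", cigar[pp])
  }
  if (any(pm)) {
    seq_sam[pm] <- paste0(err$read[pm], as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(primer_inst[pm]))))
    cigar[pm] <- paste0(cigar[pm], np, "S")
  }

  mapq <- rep(60L, n_u)
  low <- !from_target & runif(n_u) < cfg$low_mapq_fraction
  mapq[low] <- sample(0:19, sum(low), replace = TRUE)

  reads <- data.frame(reference_id = refid, start = start, end = start + L,
                      strand = strand, mapq = mapq, cigar = cigar,
                      nm = err$nm, aligned_length = err$alen,
                      seq_fastq = seq_fastq, seq_sam = seq_sam,
                      is_duplicate = FALSE, from_target = from_target,
                      stringsAsFactors = FALSE)
  if (n_dup > 0L) {
    tmpl <- sample.int(n_u, n_dup, replace = TRUE)
    dup <- reads[tmpl, , drop = FALSE]
    dup$is_duplicate <- TRUE
    reads <- rbind(reads, dup)
  }
  reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
  reads <- cbind(query_id = sprintf("read%07d", seq_len(nrow(reads))), reads,
                 stringsAsFactors = FALSE)
  rownames(reads) <- NULL

  structure(reads, class = c("chromseq_reads", "data.frame"),
            reference_lengths = setNames(Biostrings::width(truth$sequences),
                                         names(truth$sequences)))
}

# Substitution/indel injection over fixed-width reference windows.
# Each read consumes exactly L reference bases; deletions shorten the read,
# insertions lengthen it. Returns read strings (reference orientation),
# CIGARs, NM (subs + inserted + deleted bases) and aligned query lengths.
inject_errors <- function(span, L, error_rate) {
  n_u <- length(span)
  read <- span
  cigar <- rep(paste0(L, "M"), n_u)
  nm <- integer(n_u)
  alen <- rep(L, n_u)
  n_ev <- rbinom(n_u, L, error_rate)
  if (!any(n_ev > 0L))
    return(list(read = read, cigar = cigar, nm = nm, alen = alen))

  ridx <- rep.int(seq_len(n_u), n_ev)
  pos <- sample.int(L, length(ridx), replace = TRUE)
  type <- sample(c("S", "I", "D"), length(ridx), replace = TRUE,
                 prob = c(0.7, 0.15, 0.15))
  # drop coincident events at the same read position (rare)
  keep <- !duplicated(paste(ridx, pos))
  ridx <- ridx[keep]; pos <- pos[keep]; type <- type[keep]

  # substitutions, vectorized in rounds
  s_sel <- type == "S"
  if (any(s_sel)) {
    s_r <- ridx[s_sel]; s_p <- pos[s_sel]
    rank <- ave(seq_along(s_r), s_r, FUN = seq_along)
    for (r in seq_len(max(rank))) {
      i <- which(rank == r)
      orig <- substring(read[s_r[i]], s_p[i], s_p[i])
      oi <- match(orig, BASES)
      nb <- BASES[(oi - 1L + sample.int(3L, length(i), replace = TRUE)) %% 4L + 1L]
      substr(read[s_r[i]], s_p[i], s_p[i]) <- nb
    }
    tab <- tabulate(s_r, nbins = n_u)
    nm <- nm + tab
  }

  # indels, per affected read: rebuild sequence and CIGAR segment-wise
  i_sel <- type != "S"
  if (any(i_sel)) {
    ir <- ridx[i_sel]
    ip <- pos[i_sel]
    it <- type[i_sel]
    o <- order(ir, ip)
    ir <- ir[o]; ip <- ip[o]; it <- it[o]
    g_start <- which(!duplicated(ir))
    g_end <- c(g_start[-1L] - 1L, length(ir))
    ins_base <- sample(BASES, length(ir), replace = TRUE)
    for (g in seq_along(g_start)) {
      i <- ir[g_start[g]]
      sel <- g_start[g]:g_end[g]
      p <- ip[sel]
      ins <- it[sel] == "I"
      p[ins] <- pmin(p[ins], L - 1L)  # no alignment-trailing insertions
      dup <- duplicated(p)            # clamping may collide events (rare)
      p <- p[!dup]; ins <- ins[!dup]
      b <- ins_base[sel][!dup]
      s <- read[i]
      n_ev <- length(p)
      seq_parts <- character(2L * n_ev + 1L)
      cig_parts <- character(2L * n_ev + 1L)
      prev <- 0L
      k <- 0L
      for (j in seq_len(n_ev)) {
        m_end <- if (ins[j]) p[j] else p[j] - 1L  # M run before the event
        if (m_end > prev) {
          k <- k + 1L
          seq_parts[k] <- substr(s, prev + 1L, m_end)
          cig_parts[k] <- paste0(m_end - prev, "M")
        }
        k <- k + 1L
        if (ins[j]) {
          seq_parts[k] <- b[j]
          cig_parts[k] <- "1I"
        } else {
          seq_parts[k] <- ""
          cig_parts[k] <- "1D"
        }
        prev <- p[j]
      }
      if (prev < L) {
        k <- k + 1L
        seq_parts[k] <- substr(s, prev + 1L, L)
        cig_parts[k] <- paste0(L - prev, "M")
      }
      read[i] <- paste(seq_parts[seq_len(k)], collapse = "")
      cigar[i] <- paste(cig_parts[seq_len(k)], collapse = "")
      n_del <- sum(!ins)
      n_ins <- sum(ins)
      nm[i] <- nm[i] + n_del + n_ins
      alen[i] <- L - n_del + n_ins
    }
    # adjacent same-type ops (e.g. consecutive deletions) come out unmerged;
    # normalise the few affected CIGARs
    odd <- grep("D1D|I1I", cigar)
    for (i in odd) cigar[i] <- normalize_cigar(cigar[i])
  }
  list(read = read, cigar = cigar, nm = nm, alen = alen)
}

normalize_cigar <- function(cig) {
  ops <- GenomicAlignments::explodeCigarOps(cig)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)[[1L]]
  grp <- cumsum(c(TRUE, ops[-1L] != ops[-length(ops)]))
  paste0(tapply(lens, grp, sum), ops[!duplicated(grp)], collapse = "")
}

# Concrete primer sequences: ambiguity codes resolved per read.
instantiate_primer <- function(primer, k) {
  if (k == 0L) return(character(0))
  chars <- strsplit(primer, "", fixed = TRUE)[[1]]
  pieces <- vector("list", length(chars))
  for (j in seq_along(chars)) {
    s <- IUPAC_SETS[[chars[j]]]
    pieces[[j]] <- if (length(s) == 1L) rep(s, k)
                   else s[sample.int(length(s), k, replace = TRUE)]
  }
  do.call(paste0, pieces)
}

#' Write simulated reads as FASTQ and truth SAM
#'
#' The FASTQ holds reads as sequenced (primer tail first, flat Q40 quality);
#' the SAM holds the exact source alignments, coordinate-sorted, with primer
#' tails soft-clipped and an `NM` tag. Parsing the SAM with
#' [read_alignments()] recovers the generator's source intervals exactly.
#'
#' @param reads A `chromseq_reads` object.
#' @param fastq,sam Output paths; either may be `NULL` to skip.
#' @return Invisible named vector of written paths.
#' @export
write_reads <- function(reads, fastq = NULL, sam = NULL) {
  stopifnot(inherits(reads, "chromseq_reads"))
  out <- character(0)
  if (!is.null(fastq)) {
    seqs <- Biostrings::DNAStringSet(setNames(reads$seq_fastq, reads$query_id))
    quals <- Biostrings::BStringSet(strrep("I", nchar(reads$seq_fastq)))
    Biostrings::writeXStringSet(seqs, fastq, format = "fastq",
                                qualities = quals)
    out["fastq"] <- fastq
  }
  if (!is.null(sam)) {
    sam_write(data.frame(query_id = reads$query_id,
                         reference_id = reads$reference_id,
                         start = reads$start, strand = reads$strand,
                         mapq = reads$mapq, cigar = reads$cigar,
                         nm = reads$nm, seq = reads$seq_sam,
                         stringsAsFactors = FALSE),
              attr(reads, "reference_lengths"), sam)
    out["sam"] <- sam
  }
  invisible(out)
}
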