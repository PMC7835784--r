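#' Primer trimming configuration
#'
#' @param primers Character vector of IUPAC primer sequences to look for at
#'   the 5' end of each read. Default: the degenerate DOP-PCR primer.
#' @param max_mismatches Maximum mismatches allowed in a primer match.
#'   Ambiguity codes (e.g. `N`) match any compatible base and never count as
#'   mismatches.
#' @param min_length_after_trim Reads shorter than this after trimming are
#'   discarded (default 20 bp, matching the alignment-length filter
#'   downstream).
#' @param trim_3prime Also search for the reverse complement of each primer
#'   anchored at the 3' end (read-through); off by default since DOP primers
#'   are 5' tails.
#' @return A validated list of class `chromseq_trim_config`.
#' @export
trim_config <- function(primers = "CCGACTCGAGNNNNNNATGTGG",
                        max_mismatches = 2L,
                        min_length_after_trim = 20L,
                        trim_3prime = FALSE) {
  if (!is.character(primers) || length(primers) == 0L ||
      !all(vapply(primers, is_iupac, logical(1))))
    stop_config("primers", "must be non-empty IUPAC strings")
  structure(list(primers = toupper(primers),
                 max_mismatches = check_pos_int(max_mismatches,
                                                "max_mismatches", min = 0L),
                 min_length_after_trim = check_pos_int(min_length_after_trim,
                                                       "min_length_after_trim"),
                 trim_3prime = isTRUE(trim_3prime)),
            class = "chromseq_trim_config")
}

# Number of mismatches of `primer` (IUPAC) against the prefix of each read,
# anchored at position 1. Vectorized over reads; reads shorter than the
# primer get NA (no match possible).
iupac_prefix_mismatches <- function(reads, primer) {
  lp <- nchar(primer)
  mm <- integer(length(reads))
  chars <- strsplit(primer, "", fixed = TRUE)[[1]]
  for (j in seq_len(lp)) {
    allowed <- IUPAC_SETS[[chars[j]]]
    if (length(allowed) == 4L) next  # N matches anything, never a mismatch
    mm <- mm + !(substring(reads, j, j) %in% allowed)
  }
  mm[nchar(reads) < lp] <- NA_integer_
  mm
}

#' Trim WGA primer tails from reads
#'
#' For each read, the longest configured primer whose IUPAC match (at most
#' `max_mismatches` mismatches) anchors at the 5' end is removed; reads left
#' shorter than `min_length_after_trim` are discarded. With
#' `cfg$trim_3prime`, the reverse complement of each primer is additionally
#' trimmed from the 3' end. Trimming is idempotent once no primer prefix
#' remains.
#'
#' @param reads A named character vector of read sequences, a
#'   `Biostrings::QualityScaledDNAStringSet`, or a `DNAStringSet`.
#' @param cfg A [trim_config()].
#' @return A list with `reads` (same representation as the input, trimmed and
#'   filtered) and `stats`, a one-row data.frame: `input`, `trimmed`,
#'   `discarded`, `passed` (`passed + discarded == input`).
#' @examples
#' cfg <- trim_config(max_mismatches = 0)
#' trim_reads(c(r1 = paste0("CCGACTCGAGACGTCAATGTGG", strrep("ACGT", 10))), cfg)
#' @export
trim_reads <- function(reads, cfg) {
  stopifnot(inherits(cfg, "chromseq_trim_config"))
  is_xss <- methods::is(reads, "XStringSet")
  seqs <- unname(as.character(reads))
  nms <- names(reads)
  n <- length(seqs)

  trim_from <- rep(0L, n)  # bases removed at 5'
  for (p in cfg$primers[order(-nchar(cfg$primers))]) {
    cand <- trim_from == 0L
    if (!any(cand)) break
    mm <- iupac_prefix_mismatches(seqs[cand], p)
    hit <- !is.na(mm) & mm <= cfg$max_mismatches
    trim_from[cand][hit] <- nchar(p)
  }
  trim_to <- nchar(seqs)  # last base kept
  if (cfg$trim_3prime) {
    for (p in cfg$primers) {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(p)))
      lp <- nchar(p)
      suffix <- substring(seqs, pmax(trim_to - lp + 1L, 1L), trim_to)
      mm <- iupac_prefix_mismatches(suffix, rc)
      hit <- !is.na(mm) & mm <= cfg$max_mismatches
      trim_to[hit] <- trim_to[hit] - lp
    }
  }

  trimmed <- trim_from > 0L | trim_to < nchar(seqs)
  new_len <- pmax(trim_to - trim_from, 0L)
  keep <- new_len >= cfg$min_length_after_trim

  out <- if (is_xss) {
    # subseq on a QualityScaledDNAStringSet narrows sequence and quality
    # together but warns about dropped mcols; nothing of ours is lost
    suppressWarnings(Biostrings::subseq(reads[keep],
                                        start = trim_from[keep] + 1L,
                                        end = trim_to[keep]))
  } else {
    substring(seqs, trim_from + 1L, trim_to)[keep]
  }
  if (!is_xss && !is.null(nms)) names(out) <- nms[keep]

  list(reads = out,
       stats = data.frame(input = n, trimmed = sum(trimmed),
                          discarded = sum(!keep), passed = sum(keep)))
}

#' Trim a FASTQ file
#'
#' File-level wrapper around [trim_reads()] preserving per-base qualities.
#'
#' @param input Path to a FASTQ file (gzip accepted).
#' @param output Path for the trimmed FASTQ.
#' @param cfg A [trim_config()].
#' @param stats_path Optional path for a one-row TSV of trim statistics.
#' @return The trim statistics data.frame, invisibly.
#' @export
trim_fastq <- function(input, output, cfg, stats_path = NULL) {
  reads <- read_fastq(input)
  res <- trim_reads(reads, cfg)
  Biostrings::writeQualityScaledXStringSet(res$reads, output)
  if (!is.null(stats_path))
    write.table(res$stats, stats_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(res$stats)
}

#' Read a FASTQ file with qualities
#'
#' @param path FASTQ path (gzip accepted). An empty file yields an empty set.
#' @return A `Biostrings::QualityScaledDNAStringSet`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (file.size(path) == 0L)
    return(Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(), Biostrings::PhredQuality(character(0))))
  # Biostrings is permissive on read (it pads short qualities rather than
  # failing), so validate record structure first
  bad <- locate_bad_fastq_record(path)
  if (!is.na(bad))
    stop(sprintf("FASTQ parse error in '%s' at record %d", path, bad),
         call. = FALSE)
  # Biostrings parks qualities in mcols while reading and warns when the
  # QualityScaled constructor drops them again; that warning is pure noise
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# Index of the first structurally invalid FASTQ record, or NA if none:
# 4-line records, '@' title, '+' separator, matching sequence/quality widths.
locate_bad_fastq_record <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) return(length(lines) %/% 4L + 1L)
  i <- seq(1L, length(lines), by = 4L)
  ok <- startsWith(lines[i], "@") & startsWith(lines[i + 2L], "+") &
    nchar(lines[i + 1L]) == nchar(lines[i + 3L]) & nzchar(lines[i + 1L])
  if (all(ok)) NA_integer_ else which(!ok)[1L]
}
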