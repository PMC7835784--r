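# Coordinate-sorted SAM text writer shared by the simulator (truth SAM, with
# sequences) and write_alignments_sam (records only, SEQ "*").
# records: query_id, reference_id, start (0-based), strand, mapq, cigar, nm,
# and optionally seq.
sam_write <- function(records, reference_lengths, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(reference_lengths),
                       as.integer(reference_lengths))), con)
  if (nrow(records) > 0L) {
    ord <- radix_order(match(records$reference_id, names(reference_lengths)),
                       records$start, records$query_id)
    r <- records[ord, , drop = FALSE]
    seq <- if ("seq" %in% names(r)) r$seq else rep("*", nrow(r))
    qual <- ifelse(seq == "*", "*", strrep("I", nchar(seq)))
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                       r$query_id, ifelse(r$strand == "-", 16L, 0L),
                       r$reference_id, as.integer(r$start) + 1L,
                       as.integer(r$mapq), r$cigar, seq, qual,
                       as.integer(r$nm)), con)
  }
  invisible(path)
}

#' Read alignments from SAM or BAM
#'
#' Ingests primary mapped alignments into the pipeline's alignment table.
#' Unmapped, secondary and supplementary records are excluded. SAM input is
#' converted on the fly with `Rsamtools::asBam`, so both formats need a valid
#' header whose `@SQ` lines cover every reference used.
#'
#' Coordinates are converted from 1-based SAM to 0-based half-open.
#' `aligned_length` is the number of aligned query bases (CIGAR `M`/`=`/`X`/`I`
#' operations, soft clips excluded) — the quantity thresholded by the
#' alignment-length filter. `edit_distance` comes from the `NM` tag and falls
#' back to 0 (with a message) when the tag is absent.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A data.frame with columns `query_id`, `reference_id`, `start`,
#'   `end`, `strand`, `mapq`, `aligned_length`, `edit_distance`, sorted by
#'   `(reference_id, start)` in reference-header order.
#' @examples
#' \dontrun{aln <- read_alignments("sample.bam")}
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  if (is_sam) validate_sam_references(path)
  bam <- if (is_sam) {
    dest <- tempfile(fileext = "")
    tryCatch(Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                              indexDestination = FALSE),
             error = function(e) stop(sprintf(
               "SAM format error in '%s' (missing header?): %s",
               path, conditionMessage(e)), call. = FALSE))
  } else path
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("qname", "mapq"), tag = "NM")
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  nm <- S4Vectors::mcols(gal)$NM
  if (length(gal) > 0L && anyNA(nm)) {
    message(sprintf("NM tag absent for %d alignment(s); edit distance set to 0",
                    sum(is.na(nm))))
    nm[is.na(nm)] <- 0L
  }
  out <- data.frame(
    query_id = S4Vectors::mcols(gal)$qname,
    reference_id = as.character(GenomicAlignments::seqnames(gal)),
    start = IRanges::start(gal) - 1L,
    end = IRanges::end(gal),
    strand = as.character(GenomicRanges::strand(gal)),
    mapq = S4Vectors::mcols(gal)$mapq,
    aligned_length = GenomicAlignments::cigarWidthAlongQuerySpace(
      GenomicAlignments::cigar(gal), after.soft.clipping = TRUE),
    edit_distance = if (length(gal)) as.integer(nm) else integer(0),
    stringsAsFactors = FALSE)
  header_order <- as.character(GenomicAlignments::seqnames(
    GenomicRanges::seqinfo(gal)))
  out <- out[radix_order(match(out$reference_id, header_order),
                         out$start, out$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# htslib silently demotes records whose RNAME is missing from the header to
# unmapped; the contract here is a hard format error instead.
validate_sam_references <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "@")]
  if (length(hdr) == 0L)
    stop(sprintf("SAM format error in '%s': missing header", path),
         call. = FALSE)
  sq <- sub("\tLN:.*$", "", sub("^@SQ\tSN:", "", hdr[startsWith(hdr, "@SQ")]))
  sq <- sub("\t.*$", "", sq)
  rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(rec) == 0L) return(invisible(TRUE))
  rname <- sub("^[^\t]+\t[^\t]+\t([^\t]+)\t.*$", "\\1", rec)
  bad <- setdiff(unique(rname), c(sq, "*"))
  if (length(bad) > 0L)
    stop(sprintf("SAM format error in '%s': reference %s not in header",
                 path, bad[1L]), call. = FALSE)
  invisible(TRUE)
}

#' Write an alignment table back to SAM
#'
#' Inverse of [read_alignments()] for the fields the pipeline carries.
#' Sequences are not stored in alignment tables, so `SEQ`/`QUAL` are `*`; the
#' CIGAR is reconstructed so that both the reference span and the aligned
#' query length round-trip (`M` plus a trailing `I` or `D` when they differ).
#'
#' @param alignments Alignment data.frame (see [read_alignments()]).
#' @param reference_lengths Named vector of reference sequence lengths.
#' @param path Output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(alignments, reference_lengths, path) {
  a <- alignments
  span <- a$end - a$start
  alen <- a$aligned_length
  cigar <- character(nrow(a))
  eq <- alen == span
  cigar[eq] <- paste0(alen[eq], "M")
  ins <- alen > span
  cigar[ins] <- paste0(span[ins], "M", alen[ins] - span[ins], "I")
  del <- alen < span
  cigar[del] <- paste0(alen[del], "M", span[del] - alen[del], "D")
  sam_write(data.frame(query_id = a$query_id, reference_id = a$reference_id,
                       start = a$start, strand = a$strand, mapq = a$mapq,
                       cigar = cigar, nm = a$edit_distance,
                       stringsAsFactors = FALSE),
            reference_lengths, path)
}

#' Align reads with an external aligner
#'
#' Thin adapter around `bwa mem` or `minimap2`: indexes the reference if
#' needed, runs the aligner, and coordinate-sorts the output with samtools.
#' Command lines are logged with `message()` for provenance. The pipeline does
#' not require this step — the simulator's truth SAM can be ingested directly —
#' but it is the documented route for real FASTQ data.
#'
#' @param fastq Path to single-end reads (FASTQ, optionally gzipped).
#' @param reference Path to the reference FASTA.
#' @param aligner `"bwa"` or `"minimap2"`.
#' @param extra_args Character vector of additional aligner arguments.
#' @param outdir Directory for the sorted BAM (default: directory of `fastq`).
#' @return Path to the sorted BAM.
#' @export
run_external_aligner <- function(fastq, reference,
                                 aligner = c("bwa", "minimap2"),
                                 extra_args = character(), outdir = NULL) {
  aligner <- match.arg(aligner)
  for (exe in c(aligner, "samtools")) {
    if (Sys.which(exe) == "")
      stop(sprintf("required executable not found on PATH: %s", exe),
           call. = FALSE)
  }
  if (is.null(outdir)) outdir <- dirname(fastq)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bam <- file.path(outdir, paste0(
    tools::file_path_sans_ext(basename(fastq)), ".sorted.bam"))
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)

  errf <- tempfile()
  on.exit(unlink(errf), add = TRUE)
  if (aligner == "bwa") {
    if (!file.exists(paste0(reference, ".bwt"))) {
      message("running: bwa index ", reference)
      status <- system2("bwa", c("index", reference), stdout = FALSE,
                        stderr = errf)
      if (status != 0L)
        stop("bwa index failed: ",
             paste(readLines(errf, warn = FALSE), collapse = "\n"),
             call. = FALSE)
    }
    args <- c("mem", extra_args, reference, fastq)
  } else {
    args <- c("-a", "-x", "sr", extra_args, reference, fastq)
  }
  message("running: ", aligner, " ", paste(args, collapse = " "))
  status <- system2(aligner, args, stdout = sam, stderr = errf)
  if (status != 0L)
    stop(sprintf("%s failed (exit %d): %s", aligner, status,
                 paste(utils::tail(readLines(errf, warn = FALSE), 5),
                       collapse = "\n")), call. = FALSE)

  message("running: samtools sort -o ", bam)
  status <- system2("samtools", c("sort", "-o", bam, sam), stdout = FALSE,
                    stderr = errf)
  if (status != 0L)
    stop("samtools sort failed: ",
         paste(readLines(errf, warn = FALSE), collapse = "\n"), call. = FALSE)
  bam
}
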