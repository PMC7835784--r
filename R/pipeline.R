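#' Pipeline configuration
#'
#' Collects every input path and stage configuration for [run_pipeline()] in
#' one validated object. Exactly one of `fastq` (raw reads, requires
#' `aligner`) or `alignments` (SAM/BAM, e.g. the simulator's truth SAM) must
#' be given.
#'
#' @param reference Path to the reference FASTA (required; provides reference
#'   lengths and the fallback contig track).
#' @param fastq Optional path to single-end FASTQ reads.
#' @param alignments Optional path to a SAM/BAM of pre-computed alignments.
#' @param agp Optional AGP v2.1 contig map; when given it defines the contig
#'   track used for misassembly classification, otherwise contigs are derived
#'   from N runs in the FASTA.
#' @param aligner `"bwa"` or `"minimap2"`; required with `fastq`.
#' @param trim,filter,region,assign Stage configurations; see
#'   [trim_config()], [filter_config()], [region_config()], [assign_config()].
#' @param scaffold_pattern Regular expression selecting unplaced scaffolds for
#'   the assignment decision (default `"^scaffold"`).
#' @param target_reference Optional reference id of the sampled chromosome,
#'   used only for on-target reporting.
#' @param outdir Optional output directory; when set, [run_pipeline()] writes
#'   BED/TSV/JSON/AGP outputs there.
#' @param seed Integer seed recorded for provenance (the pipeline itself is
#'   deterministic; only simulation and alignment consume randomness).
#' @return A list of class `chromseq_pipeline_config`.
#' @seealso [pipeline_config_from_yaml()]
#' @export
pipeline_config <- function(reference, fastq = NULL, alignments = NULL,
                            agp = NULL, aligner = NULL,
                            trim = trim_config(), filter = filter_config(),
                            region = region_config(), assign = assign_config(),
                            scaffold_pattern = "^scaffold",
                            target_reference = NULL, outdir = NULL,
                            seed = 1L) {
  if (is.null(fastq) == is.null(alignments))
    stop_config("fastq/alignments", "exactly one input must be given")
  if (!is.null(fastq) && is.null(aligner))
    stop_config("aligner", "is required when starting from FASTQ")
  for (p in c(reference, fastq, alignments, agp)) {
    if (!is.null(p) && !file.exists(p))
      stop_config("paths", sprintf("references a missing file: %s", p))
  }
  stopifnot(inherits(trim, "chromseq_trim_config"),
            inherits(filter, "chromseq_filter_config"),
            inherits(region, "chromseq_region_config"),
            inherits(assign, "chromseq_assign_config"))
  structure(list(reference = reference, fastq = fastq, alignments = alignments,
                 agp = agp, aligner = aligner, trim = trim, filter = filter,
                 region = region, assign = assign,
                 scaffold_pattern = scaffold_pattern,
                 target_reference = target_reference, outdir = outdir,
                 seed = check_pos_int(seed, "seed", min = 0L)),
            class = "chromseq_pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' Top-level keys map to [pipeline_config()] arguments; the nested `trim`,
#' `filter`, `region` and `assign` maps are passed to the respective
#' constructors, so every threshold has the same name and default as in R.
#' Unknown keys are an error, to catch typos.
#'
#' @param path Path to a YAML configuration.
#' @return A `chromseq_pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("reference", "fastq", "alignments", "agp", "aligner", "trim",
             "filter", "region", "assign", "scaffold_pattern",
             "target_reference", "outdir", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad) > 0L)
    stop_config(bad[1L], "is not a recognised configuration key")
  for (sec in c("trim", "filter", "region", "assign")) {
    if (!is.null(y[[sec]]))
      y[[sec]] <- do.call(paste0(if (sec == "assign") "assign" else sec,
                                 "_config"), y[[sec]])
  }
  do.call(pipeline_config, y)
}

#' Run the full chromosome-assignment pipeline
#'
#' Executes trim → align (or ingest) → deduplicate → filter → merge →
#' detect regions → score/assign scaffolds → classify regions, and returns a
#' stage-by-stage summary. With `cfg$outdir` set, also writes
#' `positions.bed`, `regions.tsv`, `assignments.tsv`, `assigned.agp`,
#' `summary.json` and `summary.txt`. Re-running with identical inputs and
#' configuration produces byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return An object of class `chromseq_summary`; see [write_summary()].
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "chromseq_pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  counts <- c(raw = NA_real_, trimmed = NA_real_, mapped = 0,
              deduplicated = 0, filtered = 0, positions = 0)

  aln_path <- cfg$alignments
  if (!is.null(cfg$fastq)) {
    reads <- stage("trim", read_fastq(cfg$fastq))
    counts["raw"] <- length(reads)
    trimmed <- stage("trim", trim_reads(reads, cfg$trim))
    counts["trimmed"] <- trimmed$stats$passed
    if (length(trimmed$reads) > 0L) {
      tf <- tempfile(fileext = ".fastq")
      Biostrings::writeQualityScaledXStringSet(trimmed$reads, tf)
      aln_path <- stage("align", run_external_aligner(
        tf, cfg$reference, aligner = cfg$aligner,
        outdir = tempdir()))
    }
  }

  aln <- if (is.null(aln_path)) empty_alignments() else
    stage("ingest", read_alignments(aln_path))
  counts["mapped"] <- nrow(aln)

  dd <- stage("deduplicate", deduplicate(aln))
  counts["deduplicated"] <- nrow(dd$alignments)
  filtered <- stage("filter", filter_alignments(dd$alignments, cfg$filter))
  counts["filtered"] <- nrow(filtered)
  divergence <- if (nrow(filtered) > 0L) divergence_summary(filtered)
                else NA_real_

  positions <- stage("merge", merge_positions(filtered))
  counts["positions"] <- nrow(positions)

  track <- stage("contigs", if (!is.null(cfg$agp))
    contig_track_from_agp(cfg$agp) else contig_track_from_fasta(cfg$reference))
  fa_lengths <- reference_lengths_from_fasta(cfg$reference)
  mappable <- tapply(track$end - track$start,
                     factor(track$reference_id, levels = names(fa_lengths)),
                     sum)
  mappable[is.na(mappable)] <- 0
  mappable <- setNames(as.numeric(mappable), names(fa_lengths))

  regions <- stage("regions", detect_regions(
    positions, fa_lengths, cfg$region, genome_length = sum(mappable)))
  tol <- attr(regions, "max_gap")
  if (is.null(tol))
    tol <- if (identical(cfg$region$max_gap, "auto")) 0 else cfg$region$max_gap
  regions$label <- vapply(seq_len(nrow(regions)), function(i)
    stage("classify", classify_region(regions[i, ], track, tolerance = tol)),
    character(1))

  scores <- stage("score", score_scaffolds(positions, fa_lengths, mappable))
  assignment <- stage("assign", assign_scaffolds(
    scores, cfg$assign, scaffold_pattern = cfg$scaffold_pattern))

  by_ref <- table(factor(positions$reference_id, levels = names(fa_lengths)))
  on_target <- if (!is.null(cfg$target_reference))
    as.numeric(by_ref[cfg$target_reference]) else NA_real_

  summary <- structure(list(
    counts = counts,
    duplicate_fraction = dd$removed_fraction,
    mean_divergence = divergence,
    positions_by_reference = setNames(as.numeric(by_ref), names(fa_lengths)),
    on_target = on_target,
    target_reference = cfg$target_reference,
    regions = regions,
    assignment_table = assignment$table,
    assigned = assignment$assigned,
    assigned_bp = assignment$assigned_bp,
    max_gap = tol,
    positions = positions),
    class = "chromseq_summary")

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    write_bed(positions, file.path(cfg$outdir, "positions.bed"))
    write_bed(regions, file.path(cfg$outdir, "regions.bed"))
    write.table(regions, file.path(cfg$outdir, "regions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(assignment$table, file.path(cfg$outdir, "assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_assigned_agp(assignment$assigned,
                       chromosome_name = cfg$target_reference %||% "assigned",
                       path = file.path(cfg$outdir, "assigned.agp"))
    write_summary(summary, file.path(cfg$outdir, "summary.json"),
                  format = "json")
    writeLines(format(summary), file.path(cfg$outdir, "summary.txt"))
  }
  summary
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_alignments <- function() {
  data.frame(query_id = character(), reference_id = character(),
             start = numeric(), end = numeric(), strand = character(),
             mapq = integer(), aligned_length = integer(),
             edit_distance = integer(), stringsAsFactors = FALSE)
}

reference_lengths_from_fasta <- function(path) {
  info <- Biostrings::fasta.seqlengths(path)
  setNames(as.numeric(info), sub("\\s.*$", "", names(info)))
}

#' @export
format.chromseq_summary <- function(x, ...) {
  c0 <- function(v) if (is.na(v)) "NA"
        else format(v, big.mark = ",", scientific = FALSE)
  lines <- c(
    "chromseq pipeline summary",
    sprintf("  raw reads:            %s", c0(x$counts["raw"])),
    sprintf("  after trimming:       %s", c0(x$counts["trimmed"])),
    sprintf("  mapped:               %s", c0(x$counts["mapped"])),
    sprintf("  after deduplication:  %s (duplicate fraction %s)",
            c0(x$counts["deduplicated"]),
            if (is.na(x$duplicate_fraction)) "NA"
            else sprintf("%.3f", x$duplicate_fraction)),
    sprintf("  after filters:        %s (mean divergence %s)",
            c0(x$counts["filtered"]),
            if (is.na(x$mean_divergence)) "NA"
            else sprintf("%.4f", x$mean_divergence)),
    sprintf("  merged positions:     %s", c0(x$counts["positions"])))
  if (!is.null(x$target_reference)) {
    lines <- c(lines, sprintf(
      "  on target (%s):     %s of %s (%s, ~%s%%)", x$target_reference,
      c0(x$on_target), c0(x$counts["positions"]),
      percent_label(x$on_target, x$counts["positions"]),
      if (x$counts["positions"] == 0) "NA"
      else round(100 * x$on_target / x$counts["positions"])))
  }
  lines <- c(lines,
             sprintf("  regions detected:     %d", nrow(x$regions)),
             sprintf("  scaffolds assigned:   %d (%s bp)",
                     nrow(x$assigned), c0(x$assigned_bp)))
  lines
}

#' @export
print.chromseq_summary <- function(x, ...) {
  writeLines(format(x))
  invisible(x)
}

#' Write / read a pipeline summary
#'
#' `write_summary()` serialises the stage ledger in JSON (full: counts,
#' fractions, per-reference position counts, regions, assignments) or TSV
#' (flat key-value pairs of the scalar quantities), with a stable key order;
#' `read_summary()` re-reads either format into a list, and a JSON → TSV →
#' JSON round trip preserves all counts. Percentages are never stored — they
#' are recomputed from the integer counts at render time.
#'
#' @param summary A `chromseq_summary` from [run_pipeline()].
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly (`write_summary`); a list (`read_summary`).
#' @export
write_summary <- function(summary, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  scalars <- summary_scalars(summary)
  if (format == "json") {
    payload <- c(scalars,
                 list(positions_by_reference =
                        as.list(summary$positions_by_reference),
                      regions = summary$regions,
                      assignments = summary$assignment_table))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    tab <- data.frame(key = names(scalars),
                      value = vapply(scalars, function(v)
                        format(v, scientific = FALSE, trim = TRUE,
                               digits = 15), character(1)))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

summary_scalars <- function(s) {
  c(as.list(setNames(as.numeric(s$counts), paste0("n_", names(s$counts)))),
    list(duplicate_fraction = s$duplicate_fraction,
         mean_divergence = s$mean_divergence,
         on_target = s$on_target,
         n_regions = as.numeric(nrow(s$regions)),
         n_assigned = as.numeric(nrow(s$assigned)),
         assigned_bp = as.numeric(s$assigned_bp)))
}

#' @rdname write_summary
#' @export
read_summary <- function(path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    tab <- read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
    vals <- suppressWarnings(as.numeric(tab$value))
    setNames(as.list(ifelse(tab$value == "NA", NA_real_, vals)), tab$key)
  }
}
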