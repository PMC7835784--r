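# Shared fixtures and independent oracles, all built in code.

# A small, fast simulation: ~0.8 Mb assembly, 2000 reads.
tiny_sim_config <- function(seed = 7L, ...) {
  defaults <- list(
    seed = seed,
    chromosome_lengths = c(3e5, 2e5, 1e5),
    misassembly = list(host_chromosome = "chr1", insert_length = 5e4,
                       insert_position = 1e5),
    n_unplaced_scaffolds = 6, n_target_scaffolds = 3,
    scaffold_length_range = c(2e4, 4e4),
    contig_length_range = c(2e4, 5e4),
    n_reads = 2000)
  dots <- list(...)
  args <- utils::modifyList(defaults, dots, keep.null = TRUE)
  # modifyList(keep.null=) still strips NULL at the top level of `dots` when
  # the default is a list; force explicit NULLs through
  for (nm in names(dots)) if (is.null(dots[[nm]])) args[nm] <- list(NULL)
  do.call(sim_config, args)
}

# Build an alignment data.frame with sensible defaults for unit tests.
make_aln <- function(reference_id, start, end,
                     strand = "+", mapq = 60L,
                     aligned_length = end - start, edit_distance = 0L,
                     query_id = NULL) {
  n <- max(length(reference_id), length(start), length(end))
  if (is.null(query_id)) query_id <- sprintf("q%03d", seq_len(n))
  data.frame(query_id = query_id, reference_id = reference_id,
             start = start, end = end, strand = strand, mapq = mapq,
             aligned_length = aligned_length, edit_distance = edit_distance,
             stringsAsFactors = FALSE)
}

# Independent per-base coverage oracle for interval merging: paint a logical
# vector, then extract runs. Book-ended intervals fuse into one covered run,
# so this is the oracle for merge_adjacent = TRUE.
coverage_merge_oracle <- function(start, end, L = max(end)) {
  cov <- logical(L)
  for (i in seq_along(start)) cov[(start[i] + 1):end[i]] <- TRUE
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = as.numeric(starts[r$values]),
             end = as.numeric(ends[r$values]))
}

# Oracle for strict-overlap merging (the default): paint at half-base
# resolution so book-ended intervals leave a one-slot gap between their runs
# while genuinely overlapping intervals fuse.
strict_merge_oracle <- function(start, end, L = max(end)) {
  cov <- logical(2L * L)
  for (i in seq_along(start)) cov[(2 * start[i] + 1):(2 * end[i] - 1)] <- TRUE
  r <- rle(cov)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1
  data.frame(start = (lo[r$values] - 1) / 2, end = (hi[r$values] + 1) / 2)
}

radix_order_df <- function(df) order(df$reference_id, df$start,
                                     method = "radix")

# Independent binomial upper-tail oracle by explicit summation.
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(stats::dbinom(k:n, n, p))
}

# Write a SAM file from raw text lines (plus a standard header).
write_sam_text <- function(path, sq, records) {
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)),
               records), path)
  path
}
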