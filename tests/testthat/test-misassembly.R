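test_that("contigs are maximal non-N runs with a minimum gap length", {
  seqs <- Biostrings::DNAStringSet(c(
    a = paste0("ACGT", strrep("N", 100), "ACGT"),
    b = strrep("ACGT", 10),
    c = paste0(strrep("A", 20), strrep("N", 5), strrep("C", 20))))
  track <- contig_track_from_fasta(seqs)
  a <- track[track$reference_id == "a", ]
  expect_equal(a$start, c(0, 104))
  expect_equal(a$end, c(4, 108))
  b <- track[track$reference_id == "b", ]
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start, b$end), c(0, 40))
  # a 5-base N run stays inside the contig (below the 10 bp gap threshold)
  cc <- track[track$reference_id == "c", ]
  expect_equal(nrow(cc), 1L)
  expect_equal(c(cc$start, cc$end), c(0, 45))
})

test_that("FASTA-derived contigs reproduce the simulator's contig map exactly", {
  truth <- build_assembly(tiny_sim_config())
  track <- contig_track_from_fasta(truth$sequences)
  got <- as.data.frame(track)[radix_order_df(track),
                              c("reference_id", "start", "end")]
  want <- truth$contig_map[radix_order_df(truth$contig_map),
                           c("reference_id", "start", "end")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("AGP coordinates convert to 0-based half-open contig intervals", {
  agp <- withr::local_tempfile(fileext = ".agp")
  writeLines(c("##agp-version\t2.1",
               "chr1\t1\t1000\t1\tW\tc1\t1\t1000\t+",
               "chr1\t1001\t1100\t2\tN\t100\tcontig\tno\tna",
               "chr1\t1101\t2000\t3\tW\tc2\t1\t900\t+"), agp)
  track <- contig_track_from_agp(agp)
  expect_equal(track$start, c(0, 1100))
  expect_equal(track$end, c(1000, 2000))
})

test_that("AGP and FASTA give identical tracks for the simulated genome", {
  d <- withr::local_tempdir()
  simulate_dataset(tiny_sim_config(n_reads = 100), d)
  from_fa <- contig_track_from_fasta(file.path(d, "genome.fa"))
  from_agp <- contig_track_from_agp(file.path(d, "genome.agp"))
  cols <- c("reference_id", "start", "end")
  a <- as.data.frame(from_fa)[radix_order_df(from_fa), cols]
  b <- as.data.frame(from_agp)[radix_order_df(from_agp), cols]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("overlapping AGP components are rejected", {
  agp <- withr::local_tempfile(fileext = ".agp")
  writeLines(c("chr1\t1\t1000\t1\tW\tc1\t1\t1000\t+",
               "chr1\t900\t1900\t2\tW\tc2\t1\t1001\t+"), agp)
  expect_error(contig_track_from_agp(agp), "overlapping")
})

test_that("margin correspondence with contig ends drives the classification", {
  track <- data.frame(reference_id = "chr1",
                      start = c(0, 990, 5010), end = c(980, 5000, 8000),
                      stringsAsFactors = FALSE)
  region <- list(reference_id = "chr1", start = 1000, end = 5000)
  expect_equal(classify_region(region, track, tolerance = 50),
               "assembly_discordant")
  interior <- list(reference_id = "chr1", start = 6000, end = 7000)
  expect_equal(classify_region(interior, track, tolerance = 50),
               "putative_translocation")
  one_side <- list(reference_id = "chr1", start = 1000, end = 7000)
  expect_equal(classify_region(one_side, track, tolerance = 50),
               "indeterminate")
  expect_error(classify_region(list(reference_id = "nope", start = 0, end = 1),
                               track, 50), "contig track")
})

test_that("growing tolerance only ever moves labels toward assembly_discordant", {
  set.seed(23)
  track <- data.frame(reference_id = "c",
                      start = sort(sample(seq(0, 9e4, by = 1e4))) + 0,
                      end = sort(sample(seq(0, 9e4, by = 1e4))) + 8e3,
                      stringsAsFactors = FALSE)
  rank <- c(putative_translocation = 0, indeterminate = 1,
            assembly_discordant = 2)
  for (i in 1:30) {
    s <- runif(1, 0, 8e4)
    region <- list(reference_id = "c", start = s, end = s + runif(1, 1e3, 2e4))
    labels <- vapply(c(10, 100, 1000, 5000, 2e4), function(tol)
      classify_region(region, track, tol), character(1))
    expect_true(all(diff(rank[labels]) >= 0))
  }
})

test_that("the planted misassembly is detected and labeled assembly_discordant", {
  # high purity keeps the tiny-scale background sparse relative to max_gap
  cfg <- tiny_sim_config(n_reads = 8000, purity = 0.95)
  d <- withr::local_tempdir()
  res <- simulate_dataset(cfg, d)
  aln <- read_alignments(file.path(d, "truth.sam"))
  filtered <- filter_alignments(deduplicate(aln)$alignments, filter_config())
  pos <- merge_positions(filtered)
  lens <- setNames(as.numeric(Biostrings::width(res$truth$sequences)),
                   names(res$truth$sequences))
  regs <- detect_regions(pos, lens, region_config(max_gap = 2500))
  host <- regs[regs$reference_id == "chr1" &
               regs$end > 1e5 & regs$start < 1.5e5, ]
  expect_equal(nrow(host), 1L)
  tol <- cfg$read_length + 2500
  expect_lt(abs(host$start - 1e5), tol)
  expect_lt(abs(host$end - 1.5e5), tol)
  track <- contig_track_from_fasta(res$truth$sequences)
  expect_equal(classify_region(host, track, tolerance = 2500),
               "assembly_discordant")
})

test_that("homology overlap fractions are reported without interpretation", {
  regions <- data.frame(reference_id = "chr1", start = 1000, end = 2000,
                        n_positions = 20L, density = 20, pd = 50,
                        p_value = 1e-5, stringsAsFactors = FALSE)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t1500\tGGA2\t0\t+",
               "chr1\t1500\t3000\tGGA3\t0\t+"), bed)
  ov <- region_homology_overlap(regions, bed)
  expect_setequal(ov$homology, c("GGA2", "GGA3"))
  expect_equal(sort(ov$overlap_fraction), c(0.5, 0.5))
})
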