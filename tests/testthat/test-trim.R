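DOP <- "CCGACTCGAGNNNNNNATGTGG"

test_that("an exact degenerate-primer prefix is removed", {
  insert <- strrep("ACGTAGGCTA", 3)  # 30 bases
  read <- c(r1 = paste0("CCGACTCGAGACGTCAATGTGG", insert))
  res <- trim_reads(read, trim_config(primers = DOP, max_mismatches = 0))
  expect_equal(unname(res$reads), insert)
  expect_equal(res$stats$trimmed, 1L)
  # independent check of the anchored IUPAC match via Biostrings
  ned <- Biostrings::neditStartingAt(Biostrings::DNAString(DOP),
                                     Biostrings::DNAString(unname(read)),
                                     starting.at = 1, fixed = FALSE)
  expect_equal(ned, 0L)
})

test_that("primer-free reads pass through unchanged", {
  reads <- c(a = strrep("TTTT", 10), b = strrep("GATC", 12))
  res <- trim_reads(reads, trim_config(primers = DOP, max_mismatches = 0))
  expect_equal(res$reads, reads)
  expect_equal(res$stats$trimmed, 0L)
  expect_equal(res$stats$passed, 2L)
})

test_that("reads too short after trimming are discarded", {
  read <- paste0("CCGACTCGAGTTTTTTATGTGG", "ACG")  # 3 bases remain
  res <- trim_reads(read, trim_config(primers = DOP, max_mismatches = 0,
                                      min_length_after_trim = 20))
  expect_length(res$reads, 0L)
  expect_equal(res$stats$discarded, 1L)
  expect_equal(res$stats$passed + res$stats$discarded, res$stats$input)
})

test_that("mismatch budget is honoured and N positions never count", {
  insert <- strrep("AACCGGTT", 5)
  base <- paste0("CCGACTCGAGACGTCAATGTGG", insert)
  one_mm <- paste0("GCGACTCGAGACGTCAATGTGG", insert)  # C->G at position 1
  expect_equal(unname(trim_reads(one_mm, trim_config(primers = DOP,
    max_mismatches = 1))$reads), insert)
  res0 <- trim_reads(one_mm, trim_config(primers = DOP, max_mismatches = 0))
  expect_equal(unname(res0$reads), one_mm)
  # the six N positions can be anything without consuming the budget
  expect_equal(unname(trim_reads(base, trim_config(primers = DOP,
    max_mismatches = 0))$reads), insert)
})

test_that("trimming is idempotent once no primer prefix remains", {
  cfg <- tiny_sim_config(n_reads = 400)
  d <- withr::local_tempdir()
  simulate_dataset(cfg, d)
  reads <- read_fastq(file.path(d, "reads.fastq"))
  t1 <- trim_reads(reads, trim_config(primers = DOP))
  t2 <- trim_reads(t1$reads, trim_config(primers = DOP))
  expect_equal(as.character(t2$reads), as.character(t1$reads))
  expect_lte(length(t1$reads), length(reads))
})

test_that("3' read-through trimming removes the reverse-complemented primer", {
  insert <- strrep("ACGTTGCA", 5)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    "CCGACTCGAGACGTCAATGTGG")))
  read <- paste0(insert, rc)
  res <- trim_reads(read, trim_config(primers = DOP, max_mismatches = 0,
                                      trim_3prime = TRUE))
  expect_equal(unname(res$reads), insert)
})

test_that("malformed FASTQ is reported with the record index", {
  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "@r2", "ACGTA", "+", "III"), bad)  # quality length mismatch
  expect_error(read_fastq(bad), "record 2")
})

test_that("trim_fastq writes trimmed reads with qualities intact", {
  cfg <- tiny_sim_config(n_reads = 200)
  d <- withr::local_tempdir()
  simulate_dataset(cfg, d)
  out <- file.path(d, "trimmed.fastq")
  stats <- trim_fastq(file.path(d, "reads.fastq"), out,
                      trim_config(primers = DOP))
  expect_true(file.exists(out))
  back <- read_fastq(out)
  expect_equal(length(back), stats$passed)
  expect_true(all(Biostrings::width(Biostrings::quality(back)) ==
                  Biostrings::width(back)))
})
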