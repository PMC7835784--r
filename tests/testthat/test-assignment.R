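test_that("scores cover every reference with exact binomial tails", {
  pos <- data.frame(reference_id = rep(c("chr1", "s1"), c(90, 10)),
                    start = c(seq(0, 89) * 1e4, seq(0, 9) * 100),
                    end = c(seq(0, 89) * 1e4 + 50, seq(0, 9) * 100 + 50),
                    n_reads = 1L)
  lens <- c(chr1 = 1e6, s1 = 1e4, s2 = 5e4)
  sc <- score_scaffolds(pos, lens)
  expect_equal(sc$reference_id, names(lens))
  # scaffold with zero positions: certain tail, expected count n * L / G
  expect_equal(sc$p_value[sc$reference_id == "s2"], 1)
  expect_equal(sc$expected[sc$reference_id == "s2"], 100 * 5e4 / sum(lens))
  # exact oracle agreement
  for (i in seq_len(nrow(sc))) {
    expect_equal(sc$p_value[i],
                 binom_tail_oracle(sc$n_positions[i], 100,
                                   lens[[sc$reference_id[i]]] / sum(lens)),
                 tolerance = 1e-12)
  }
})

test_that("a scaffold spanning the whole genome is never significant", {
  pos <- data.frame(reference_id = "s1", start = seq(0, 990, by = 10),
                    end = seq(0, 990, by = 10) + 5, n_reads = 1L)
  sc <- score_scaffolds(pos, c(s1 = 1e4))
  expect_equal(sc$p_value, 1)
})

test_that("strong enrichment produces vanishing p-values", {
  # expected 2 positions, observed 40
  pos <- data.frame(reference_id = rep(c("bg", "s1"), c(19960, 40)),
                    start = c(seq_len(19960) * 100, seq_len(40) * 10),
                    end = c(seq_len(19960) * 100 + 5, seq_len(40) * 10 + 5),
                    n_reads = 1L)
  lens <- c(bg = 1e8 - 1e4, s1 = 1e4)  # scaffold fraction 1e-4
  sc <- score_scaffolds(pos, lens)
  p <- sc$p_value[sc$reference_id == "s1"]
  expect_lt(p, 1e-20)
  expect_equal(p, binom_tail_oracle(40, 20000, 1e-4), tolerance = 1e-9)
})

test_that("assignment requires both the count and the significance rule", {
  sc <- data.frame(reference_id = c("s1", "s2", "s3"),
                   length = c(1e5, 1e5, 1e5),
                   n_positions = c(14L, 100L, 40L),
                   expected = c(2, 80, 5),
                   p_value = c(1e-6, 0.2, 1e-8),
                   pd = NA_real_, stringsAsFactors = FALSE)
  res <- assign_scaffolds(sc, assign_config())
  expect_equal(res$assigned$reference_id, "s3")   # s1 fails count, s2 fails p
  expect_equal(res$assigned_bp, 1e5)
  # boundary: exactly 15 positions passes the count rule, p == alpha fails
  sc$n_positions <- c(15L, 15L, 15L)
  sc$p_value <- c(0.05, 0.049, 0.051)
  res2 <- assign_scaffolds(sc, assign_config())
  expect_equal(res2$assigned$reference_id, "s2")
})

test_that("the scaffold pattern restricts which sequences can be assigned", {
  sc <- data.frame(reference_id = c("chr1", "scaffold_001"),
                   length = c(1e6, 1e5), n_positions = c(500L, 50L),
                   expected = c(100, 2), p_value = c(1e-30, 1e-10),
                   pd = NA_real_, stringsAsFactors = FALSE)
  res <- assign_scaffolds(sc, assign_config(), scaffold_pattern = "^scaffold")
  expect_equal(res$assigned$reference_id, "scaffold_001")
})

test_that("Benjamini-Hochberg adjustment is applied when requested", {
  # one nominally significant scaffold among nineteen null ones
  sc <- data.frame(reference_id = sprintf("s%02d", 1:20),
                   length = 1e5, n_positions = 20L, expected = 5,
                   p_value = c(0.04, rep(0.9, 19)), pd = NA_real_,
                   stringsAsFactors = FALSE)
  raw <- assign_scaffolds(sc, assign_config(adjust = "none"))
  expect_equal(raw$assigned$reference_id, "s01")
  bh <- assign_scaffolds(sc, assign_config(adjust = "BH"))
  expect_equal(nrow(bh$assigned), 0L)  # 0.04 adjusts to 0.04 * 20 / 1 = 0.8
  expect_equal(bh$table$p_adjusted, p.adjust(sc$p_value, method = "BH"))
})

test_that("assignment is invariant under permutation of the score table", {
  set.seed(17)
  sc <- data.frame(reference_id = sprintf("s%03d", 1:50), length = 1e5,
                   n_positions = sample(0:60, 50, replace = TRUE),
                   expected = 10,
                   p_value = runif(50), pd = NA_real_,
                   stringsAsFactors = FALSE)
  a1 <- assign_scaffolds(sc, assign_config())
  a2 <- assign_scaffolds(sc[sample.int(50), ], assign_config())
  expect_setequal(a1$assigned$reference_id, a2$assigned$reference_id)
  expect_equal(a1$assigned_bp, a2$assigned_bp)
})

test_that("under a background-only null the assignment rate stays within alpha", {
  # 50 scaffolds tiling the genome, positions uniform: the expected count per
  # scaffold (20) clears the count rule often, so the p < 0.05 rule is the
  # binding one and its false-positive rate is what is being calibrated
  set.seed(1203)
  lens <- setNames(rep(2e4, 50), sprintf("s%02d", 1:50))
  assigned_frac <- vapply(1:100, function(rep) {
    starts <- sample.int(1e6, 1000) - 1L
    ref <- names(lens)[pmin(starts %/% 2e4 + 1L, 50L)]
    pos <- data.frame(reference_id = ref, start = starts %% 2e4,
                      end = starts %% 2e4 + 1, n_reads = 1L,
                      stringsAsFactors = FALSE)
    sc <- score_scaffolds(pos, lens)
    nrow(assign_scaffolds(sc, assign_config())$assigned) / 50
  }, numeric(1))
  # binomial SD of the per-replicate fraction at alpha = 0.05, n = 50
  expect_lte(mean(assigned_frac), 0.05 + 2 * sqrt(0.05 * 0.95 / 50) / 10)
})

test_that("positions on unknown references are a contract error", {
  pos <- data.frame(reference_id = "mystery", start = 0, end = 10, n_reads = 1L)
  expect_error(score_scaffolds(pos, c(chr1 = 1e6)), "mystery")
})

test_that("planted target scaffolds are recovered and decoys rejected on synthetic data", {
  cfg <- tiny_sim_config(n_reads = 4000)
  d <- withr::local_tempdir()
  res <- simulate_dataset(cfg, d)
  aln <- read_alignments(file.path(d, "truth.sam"))
  filtered <- filter_alignments(deduplicate(aln)$alignments, filter_config())
  pos <- merge_positions(filtered)
  lens <- setNames(as.numeric(Biostrings::width(res$truth$sequences)),
                   names(res$truth$sequences))
  sc <- score_scaffolds(pos, lens)
  out <- assign_scaffolds(sc, assign_config(), scaffold_pattern = "^scaffold")
  mem <- res$truth$membership
  planted <- mem$reference_id[mem$membership == "target" &
                              grepl("^scaffold", mem$reference_id)]
  eligible <- sc$reference_id[sc$reference_id %in% planted &
                              sc$n_positions >= 15L]
  expect_true(all(eligible %in% out$assigned$reference_id))
  expect_equal(setdiff(out$assigned$reference_id, planted), character(0))
})
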