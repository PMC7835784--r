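test_that("positions chain into regions by the start-to-start gap rule", {
  pos <- data.frame(reference_id = "chr1",
                    start = c(0, 5e3, 10e3, 15e3, 500e3, 505e3, 510e3),
                    end = c(0, 5e3, 10e3, 15e3, 500e3, 505e3, 510e3) + 100,
                    n_reads = 1L)
  cfg <- region_config(max_gap = 100e3, min_region_positions = 3L)
  regs <- detect_regions(pos, c(chr1 = 1e6), cfg)
  expect_equal(nrow(regs), 2L)
  expect_equal(regs$n_positions, c(4L, 3L))
  expect_equal(regs$start, c(0, 500e3))
  expect_equal(regs$end, c(15e3 + 100, 510e3 + 100))
})

test_that("positions all farther apart than max_gap yield no regions", {
  pos <- data.frame(reference_id = "chr1", start = seq(0, 9e5, by = 1e5),
                    end = seq(0, 9e5, by = 1e5) + 100, n_reads = 1L)
  regs <- detect_regions(pos, c(chr1 = 1e6),
                         region_config(max_gap = 5e4,
                                       min_region_positions = 2L))
  expect_equal(nrow(regs), 0L)
  expect_equal(nrow(detect_regions(pos[0, ], c(chr1 = 1e6),
                                   region_config())), 0L)
})

test_that("auto max_gap is a fraction of the expected genome-wide spacing", {
  # 100 positions over 1 Mb: expected spacing 10 kb, auto gap 2.5 kb
  starts <- c(seq(0, 49 * 2e3, by = 2e3),          # 50 tightly spaced
              seq(5e5, 5e5 + 49 * 9e3, by = 9e3))  # 50 spaced beyond the gap
  pos <- data.frame(reference_id = "chr1", start = starts, end = starts + 100,
                    n_reads = 1L)
  regs <- detect_regions(pos, c(chr1 = 1e6),
                         region_config(max_gap = "auto",
                                       min_region_positions = 15L))
  expect_equal(attr(regs, "max_gap"), (1e6 / 100) / 4)
  expect_equal(nrow(regs), 1L)
  expect_equal(regs$n_positions, 50L)
  expect_equal(regs$start, 0)
})

test_that("region calls carry density and pd consistent with their definition", {
  starts <- seq(0, 14 * 500, by = 500)
  pos <- data.frame(reference_id = "c", start = starts, end = starts + 100,
                    n_reads = 1L)
  regs <- detect_regions(pos, c(c = 1e5),
                         region_config(max_gap = 1000,
                                       min_region_positions = 15L))
  expect_equal(nrow(regs), 1L)
  span <- regs$end - regs$start
  expect_equal(regs$density, regs$n_positions / (span / 1000))
  expect_equal(regs$pd, 500)
})

test_that("the enrichment p-value is an exact binomial upper tail", {
  expect_equal(region_pvalue(0, 100, 1, 100), 1)
  expect_equal(region_pvalue(100, 100, 100, 100), 1)
  p <- region_pvalue(5, 100, 1, 100)
  expect_equal(p, binom_tail_oracle(5, 100, 0.01), tolerance = 1e-12)
  expect_equal(p, 3.66e-3, tolerance = 0.02)
  # Poisson(1) cross-check on the same tail
  expect_equal(p, 1 - stats::ppois(4, 1), tolerance = 0.02)
  set.seed(9)
  for (i in 1:60) {
    n <- sample(1:1000, 1)
    k <- sample(0:n, 1)
    frac <- runif(1, 1e-4, 0.99)
    ours <- region_pvalue(k, n, frac, 1)
    oracle <- binom_tail_oracle(k, n, frac)
    expect_lt(abs(ours - oracle), 1e-9 * max(oracle, 1e-300))
  }
})

test_that("p-values are monotone in the observed count and guarded", {
  p <- vapply(1:50, function(k) region_pvalue(k, 100, 5e3, 1e6), numeric(1))
  expect_true(all(diff(p) <= 0))
  expect_error(region_pvalue(5, 100, 2e6, 1e6), "span")
  expect_error(region_pvalue(50, 10, 1, 100), "n_total")
})

test_that("the pd statistic is the mean start-to-start gap", {
  expect_equal(pd_statistic(c(100, 200, 400)), 150)
  expect_equal(pd_statistic(c(400, 100, 200)), 150)  # order-free
  expect_equal(pd_statistic(seq(0, 900, by = 90)), 90)
  expect_error(pd_statistic(5), "fewer than two")
  # uniform positions: mean gap approaches L/n (order-statistics oracle)
  set.seed(13)
  s <- sort(runif(20000, 0, 1e6))
  expect_equal(pd_statistic(s), 1e6 / 20000, tolerance = 0.02)
})

test_that("regions are disjoint and each position joins at most one region", {
  set.seed(31)
  starts <- sort(sample(0:2e6, 800))
  pos <- data.frame(reference_id = "chr1", start = starts, end = starts + 100,
                    n_reads = 1L)
  regs <- detect_regions(pos, c(chr1 = 2e6),
                         region_config(max_gap = 3000,
                                       min_region_positions = 3L))
  if (nrow(regs) > 1L) {
    expect_true(all(regs$start[-1] >= regs$end[-nrow(regs)]))
  }
  covered <- sum(vapply(seq_len(nrow(regs)), function(i)
    sum(pos$start >= regs$start[i] & pos$start < regs$end[i]), numeric(1)))
  expect_equal(covered, sum(regs$n_positions))
})
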