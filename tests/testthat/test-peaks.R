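test_that("manual boundaries select bins by left edge, inclusive-left", {
  flat <- flat_correlogram(base = 4)
  p <- peak_manual(flat, -0.005, 0.005)
  expect_equal(p$n_bins, 10L)
  expect_equal(p$bin_lefts[1], -0.005)
  expect_equal(p$bin_lefts[p$n_bins], 0.004)  # left edge 0.005 excluded
  expect_equal(p$threshold, 4)
  expect_true(p$significant)
  expect_false(p$fallback)
  expect_error(peak_manual(flat, -0.2, 0), "within")
  expect_error(peak_manual(flat, 0.01, 0.01), "left_s < right_s")
})

test_that("cumsum peak detection matches the hand-computed crossing example", {
  h <- flat_correlogram(base = 5, peak_lefts = c(-0.001, 0, 0.001),
                        peak_count = 11)
  p <- peak_cumsum(h)
  expect_equal(p$bin_lefts, c(-0.001, 0, 0.001))
  expect_true(p$significant)
  expect_false(p$fallback)
  expect_equal(p$threshold, 5)        # baseline sd is 0 here
  expect_equal(p$expected_per_bin, 5)
  expect_equal(p$duration, 0.003)
  expect_equal(p$center, 0)
})

test_that("degenerate cumsum falls back to the +/-5 ms default region", {
  flat <- flat_correlogram(base = 4)
  p <- peak_cumsum(flat)
  expect_true(p$fallback)
  expect_false(p$significant)
  expect_equal(p$n_bins, 10L)
  expect_equal(p$duration, 0.010)
  expect_equal(range(p$bin_lefts), c(-0.005, 0.004))
})

test_that("an insignificant cumsum peak also falls back to +/-5 ms", {
  # noisy baseline, modest central bump: crossings exist but the mean peak
  # count cannot clear mean + 1.96 sd of the baseline
  lefts <- seq(-100, 100) * 0.001
  counts <- rep(c(2, 6), length.out = 201)
  counts[99:103] <- 7
  h <- as_correlogram(tibble::tibble(bin_left = lefts, count = counts))
  p <- peak_cumsum(h)
  expect_false(p$significant)
  expect_true(p$fallback)
  expect_equal(p$n_bins, 10L)
})

test_that("the shuffled-null threshold follows the population-SD formula", {
  expect_equal(motorsync:::significance_threshold(c(1, 2, 3)),
               2 + 1.96 * sqrt(2 / 3))
  expect_equal(motorsync:::significance_threshold(rep(7, 40)), 7)
})

test_that("the shuffled null is seed-reproducible and count-conserving", {
  withr::local_seed(2)
  h <- bin_intervals(stats::runif(600, -0.12, 0.12))
  n1 <- shuffled_null(h, mean_isi = 0.1, seed = 42)
  n2 <- shuffled_null(h, mean_isi = 0.1, seed = 42)
  expect_identical(n1$counts, n2$counts)
  expect_identical(n1$threshold, n2$threshold)
  expect_equal(sum(n1$counts$count), attr(h, "n_intervals"))
  expect_true(all(abs(n1$counts$bin_left) <= 0.1 + 1e-9))
  expect_equal(n1$seed, 42L)

  n3 <- shuffled_null(h, mean_isi = 0.1, seed = 43)
  expect_false(identical(n1$counts$count, n3$counts$count))
  # thresholds vary only by sampling error around mean + 1.96 sd(Poisson-ish)
  m <- 600 / 200
  expect_lt(abs(n1$threshold - (m + 1.96 * sqrt(m))), 3)

  expect_error(shuffled_null(h, mean_isi = 0, seed = 1), "positive")
  expect_error(shuffled_null(h, mean_isi = 0.1), "seed")
})

test_that("zscore peaks test only +/-10 ms, bins need not be adjacent", {
  h <- flat_correlogram(base = 4, peak_lefts = c(-0.003, 0.002, 0.05),
                        peak_count = 30)
  null <- shuffled_null(h, mean_isi = 0.1, seed = 7)
  expect_gt(null$threshold, 4)
  expect_lt(null$threshold, 30)
  p <- peak_zscore(h, null)
  expect_equal(p$bin_lefts, c(-0.003, 0.002))  # 0.05 outside the test region
  expect_true(p$significant)
  expect_equal(p$duration, 0.002)
  expect_equal(p$threshold, null$threshold)
  expect_equal(p$seed, 7L)

  quiet <- flat_correlogram(base = 4)
  p0 <- peak_zscore(quiet, shuffled_null(quiet, mean_isi = 0.1, seed = 7))
  expect_equal(p0$n_bins, 0L)
  expect_false(p0$significant)

  single <- flat_correlogram(base = 4, peak_lefts = 0, peak_count = 30)
  p1 <- peak_zscore(single, shuffled_null(single, mean_isi = 0.1, seed = 7))
  expect_equal(p1$bin_lefts, 0)
  expect_equal(p1$duration, attr(single, "binwidth"))
})

test_that("all three methods agree on an idealized rectangular peak", {
  h <- flat_correlogram(base = 4, peak_lefts = seq(-2, 2) * 0.001,
                        peak_count = 14)
  want <- seq(-2, 2) * 0.001
  expect_equal(peak_manual(h, -0.002, 0.003)$bin_lefts, want)
  expect_equal(peak_cumsum(h)$bin_lefts, want)
  pz <- peak_zscore(h, shuffled_null(h, mean_isi = 0.1, seed = 3))
  expect_equal(pz$bin_lefts, want)
})
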