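test_that("binning the printed intervals puts one count per printed bin", {
  iv <- c(-0.065, 0.015, -0.022, 0.045, -0.048, 0.008)
  h <- bin_intervals(iv, binwidth = 0.001)
  hits <- h$bin_left[h$count == 1]
  expect_equal(sort(hits), sort(iv), tolerance = 1e-9)
  expect_equal(sum(h$count), 6L)
  expect_true(all(h$count[!round(h$bin_left, 9) %in% round(iv, 9)] == 0))
  # zero-padded to the full +/-100 ms analysis window
  expect_lte(min(h$bin_left), -0.1)
  expect_gte(max(h$bin_left), 0.1 - 1e-9)
})

test_that("bins are half-open with zero as a left edge", {
  h <- bin_intervals(0.0, binwidth = 0.001)
  expect_equal(h$bin_left[h$count == 1], 0)
  h2 <- bin_intervals(c(-1e-13, 1e-4), binwidth = 0.001)
  expect_equal(sum(h2$count[h2$bin_left == 0]), 2L)  # edge snap + interior
  expect_error(bin_intervals(numeric(0)), "no intervals")
  expect_error(bin_intervals(0.1, binwidth = 0), "positive")
})

test_that("counts are conserved and each interval is recoverable to a bin", {
  withr::local_seed(4)
  for (i in 1:20) {
    iv <- stats::runif(sample(10:300, 1), -0.25, 0.25)
    bw <- sample(c(0.001, 0.002, 0.005), 1)
    h <- bin_intervals(iv, binwidth = bw)
    expect_equal(sum(h$count), length(iv))
    expect_equal(diff(h$bin_left), rep(bw, nrow(h) - 1), tolerance = 1e-9)
    # direct tally oracle: every interval lies inside its claimed bin
    tal <- table(findInterval(iv, c(h$bin_left, max(h$bin_left) + bw)))
    expect_equal(unname(h$count[as.integer(names(tal))]), as.vector(tal))
  }
})

test_that("baseline statistics use only the +/-(60-100) ms bins, population SD", {
  flat <- flat_correlogram(base = 4)
  expect_equal(baseline_stats(flat)$baseline_mean, 4)
  expect_equal(baseline_stats(flat)$baseline_sd, 0)
  expect_equal(baseline_stats(flat)$n_bins, 80L)

  # arbitrary baseline multiset, checked against the direct formula
  lefts <- seq(-100, 100) * 0.001
  counts <- rep(5, 201)
  base_idx <- which((lefts >= -0.1 & lefts + 0.001 <= -0.06 + 1e-9) |
                      (lefts >= 0.06 & lefts + 0.001 <= 0.1 + 1e-9))
  counts[base_idx] <- rep_len(c(1, 2, 3), length(base_idx))
  h <- as_correlogram(tibble::tibble(bin_left = lefts, count = counts))
  b <- counts[base_idx]
  expect_equal(baseline_stats(h)$baseline_mean, sum(b) / length(b))
  expect_equal(baseline_stats(h)$baseline_sd,
               sqrt(sum((b - mean(b))^2) / length(b)))

  # perturbing bins inside +/-60 ms leaves baseline stats unchanged
  counts2 <- counts
  counts2[lefts > -0.05 & lefts < 0.05] <- 50
  h2 <- as_correlogram(tibble::tibble(bin_left = lefts, count = counts2))
  expect_equal(baseline_stats(h2), baseline_stats(h))
})

test_that("normalized cumulative sum follows the hand-computed example", {
  flat <- flat_correlogram(base = 5)
  expect_equal(normalized_cumsum(flat)$cusum, rep(0, 201))

  h <- flat_correlogram(base = 5, peak_lefts = c(-0.001, 0, 0.001),
                        peak_count = 11)
  cs <- normalized_cumsum(h)
  steps <- diff(c(0, cs$cusum))
  expect_equal(steps[match(round(c(-0.001, 0, 0.001), 9), round(cs$bin_left, 9))],
               rep(1.2, 3))
  expect_equal(cs$cusum[length(cs$cusum)], 3.6)
  # identity: final value == (window total - n_bins * baseline mean)/baseline mean
  w_total <- sum(h$count)
  expect_equal(cs$cusum[201], (w_total - 201 * 5) / 5)

  # reversing the histogram leaves the final plateau unchanged
  mirr <- as_correlogram(tibble::tibble(bin_left = h$bin_left,
                                        count = rev(h$count)))
  expect_equal(normalized_cumsum(mirr)$cusum[201], cs$cusum[201])

  zero <- flat_correlogram(base = 0, peak_lefts = 0, peak_count = 3)
  expect_error(normalized_cumsum(zero), "longer trains or.*wider bins")
})

test_that("correlograms export to a two-column CSV and re-import identically", {
  h <- bin_intervals(c(-0.065, 0.015, 0.0081), binwidth = 0.001)
  f <- withr::local_tempfile(fileext = ".csv")
  write_correlogram(h, f)
  x <- readr::read_csv(f, show_col_types = FALSE)
  h2 <- as_correlogram(tibble::tibble(bin_left = x$bin_left_s, count = x$count))
  expect_equal(h2$count, h$count)
  expect_equal(baseline_stats(h2), baseline_stats(h))
})
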