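# Uniform peak contract shared by the three detection methods.
# `threshold` is the per-bin significance value the method tested against;
# `expected_per_bin` is the per-bin chance count the indices divide by:
# the baseline mean for the manual and cumsum methods, the shuffled-null
# significance threshold for the z-score method.
new_peak_region <- function(method, hist, bin_lefts, threshold,
                            expected_per_bin, significant, fallback,
                            seed = NULL) {
  bin_lefts <- sort(bin_lefts)
  n <- length(bin_lefts)
  bw <- attr(hist, "binwidth")
  center <- if (n == 0) NA_real_ else bin_lefts[ceiling(n / 2)]
  structure(
    list(method = method,
         bin_lefts = bin_lefts,
         n_bins = n,
         binwidth = bw,
         boundaries = if (n > 0) c(bin_lefts[1], bin_lefts[n] + bw) else c(NA_real_, NA_real_),
         duration = n * bw,
         center = center,
         threshold = threshold,
         expected_per_bin = expected_per_bin,
         significant = significant,
         fallback = fallback,
         seed = seed),
    class = "peak_region")
}

#' @export
print.peak_region <- function(x, ...) {
  cat(sprintf(
    "<peak_region: %s> %d bin(s) in [%.4g, %.4g) s; threshold %.4g; significant: %s%s\n",
    x$method, x$n_bins, x$boundaries[1], x$boundaries[2], x$threshold,
    x$significant, if (x$fallback) " (fallback +/-5 ms)" else ""))
  invisible(x)
}

# bins wholly within +/- half_width of zero lag
central_bins <- function(hist, half_width) {
  bw <- attr(hist, "binwidth")
  tol <- bw * 1e-6
  lefts <- hist$bin_left
  lefts[lefts >= -half_width - tol & lefts + bw <= half_width + tol]
}

#' Manually bounded peak (visual method)
#'
#' The oldest peak-determination approach: an investigator inspects the
#' normalized cumulative sum (see [normalized_cumsum()] and
#' [plot_cumsum()]) and supplies the peak boundaries where the deflection
#' near lag 0 begins and ends. Bins whose left edge lies in
#' `[left_s, right_s)` form the peak; the per-bin chance count is the
#' baseline mean, and the peak is significant by the investigator's
#' judgement.
#'
#' @param hist A `correlogram`.
#' @param left_s,right_s Peak boundaries in seconds, inside the +/-100 ms
#'   analysis window, `left_s < right_s`.
#' @return A `peak_region`.
#' @export
peak_manual <- function(hist, left_s, right_s) {
  stopifnot(inherits(hist, "correlogram"))
  window <- attr(hist, "window")
  if (!is.finite(left_s) || !is.finite(right_s) || left_s >= right_s) {
    stop("need finite boundaries with left_s < right_s", call. = FALSE)
  }
  if (left_s < -window || right_s > window) {
    stop(sprintf("boundaries must lie within +/-%g s of zero lag", window),
         call. = FALSE)
  }
  bw <- attr(hist, "binwidth")
  tol <- bw * 1e-6
  lefts <- hist$bin_left[hist$bin_left >= left_s - tol &
                           hist$bin_left < right_s - tol]
  bm <- attr(hist, "baseline_mean")
  new_peak_region("visual", hist, lefts, threshold = bm,
                  expected_per_bin = bm, significant = TRUE, fallback = FALSE)
}

#' Algorithmic cumulative-sum peak detection
#'
#' Finds the steep deflection of the normalized cumulative sum: the peak
#' runs from the first bin at which the cumulative sum reaches 10% of its
#' range (minimum to maximum over the +/-100 ms window) to the first bin at
#' which it reaches 90%, inclusive. The peak is significant if its mean bin
#' count exceeds the baseline mean plus 1.96 baseline SDs. When the test
#' fails — or when the baseline is so variable that the 90% crossing
#' precedes the 10% crossing, or the cumulative sum has zero range — the
#' method falls back to the default +/-5 ms region with
#' `significant = FALSE`; indices are then computed from that region.
#' A noisy baseline can make the 10–90% span unreasonably wide, so inspect
#' the cumulative sum when results look surprising.
#'
#' @param hist A `correlogram`.
#' @return A `peak_region` with `fallback = TRUE` when the +/-5 ms default
#'   region was used.
#' @export
peak_cumsum <- function(hist) {
  stopifnot(inherits(hist, "correlogram"))
  cs <- normalized_cumsum(hist)
  bm <- attr(hist, "baseline_mean")
  bsd <- attr(hist, "baseline_sd")
  sig_threshold <- bm + 1.96 * bsd
  rng <- max(cs$cusum) - min(cs$cusum)
  fallback_region <- function(significant) {
    new_peak_region("cumsum", hist, central_bins(hist, 0.005),
                    threshold = sig_threshold, expected_per_bin = bm,
                    significant = significant, fallback = TRUE)
  }
  if (rng == 0) return(fallback_region(FALSE))
  lo <- min(cs$cusum) + 0.10 * rng
  hi <- min(cs$cusum) + 0.90 * rng
  i_lo <- which(cs$cusum >= lo)[1]
  i_hi <- which(cs$cusum >= hi)[1]
  if (i_hi < i_lo) return(fallback_region(FALSE))
  lefts <- cs$bin_left[i_lo:i_hi]
  counts <- hist$count[match(lefts, hist$bin_left)]
  significant <- mean(counts) > sig_threshold
  if (!significant) return(fallback_region(FALSE))
  new_peak_region("cumsum", hist, lefts, threshold = sig_threshold,
                  expected_per_bin = bm, significant = TRUE, fallback = FALSE)
}

# population-SD significance threshold: mean + 1.96 * sqrt(sum((x-xbar)^2)/n)
significance_threshold <- function(counts) {
  m <- mean(counts)
  m + 1.96 * sqrt(mean((counts - m)^2))
}

#' Shuffled-null histogram and its significance threshold
#'
#' Builds the surrogate histogram used by the z-score method: the same
#' number of intervals as the experimental histogram, redistributed
#' uniformly over plus/minus the mean interspike interval of the slower
#' unit, then binned with the same bin convention. This preserves the
#' count-by-count sampling variability while removing any dependence
#' between the trains, modelling the null hypothesis of independent
#' discharge. The 95% significance threshold is the mean of the shuffled
#' bin counts plus 1.96 times their population SD.
#'
#' A single shuffled realization is drawn per analysis, so the seed is
#' mandatory and recorded in the result.
#'
#' @param hist The experimental `correlogram`.
#' @param mean_isi Mean ISI (s) of the slower unit (the larger of the two
#'   units' mean ISIs).
#' @param seed Integer seed for the uniform draw (applied locally; the
#'   global RNG state is untouched).
#' @return A `shuffled_null`: list with `counts` (tibble `bin_left`,
#'   `count`), `threshold`, `n_samples`, `sample_range` and `seed`.
#' @export
shuffled_null <- function(hist, mean_isi, seed) {
  stopifnot(inherits(hist, "correlogram"))
  if (!is.finite(mean_isi) || mean_isi <= 0) {
    stop("`mean_isi` must be positive", call. = FALSE)
  }
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("`seed` is required: the null is a single random realization",
         call. = FALSE)
  }
  n <- attr(hist, "n_intervals")
  if (n == 0) stop("histogram contains no intervals", call. = FALSE)
  bw <- attr(hist, "binwidth")
  sample <- withr::with_seed(as.integer(seed),
                             stats::runif(n, -mean_isi, mean_isi))
  k <- bin_index(sample, bw)
  k_lo <- min(k)
  counts <- tabulate(k - k_lo + 1L, nbins = max(k) - k_lo + 1L)
  structure(
    list(counts = tibble::tibble(bin_left = seq(k_lo, max(k)) * bw,
                                 count = as.integer(counts)),
         threshold = significance_threshold(counts),
         n_samples = n,
         sample_range = mean_isi,
         seed = as.integer(seed)),
    class = "shuffled_null")
}

#' @export
print.shuffled_null <- function(x, ...) {
  cat(sprintf(
    "<shuffled_null> %d samples over +/-%.4g s; threshold %.4g (seed %d)\n",
    x$n_samples, x$sample_range, x$threshold, x$seed))
  invisible(x)
}

#' Z-score peak detection against a shuffled null
#'
#' Tests each bin within 10 ms of zero lag individually against the
#' shuffled-null significance threshold (see [shuffled_null()]). Bins whose
#' count exceeds the threshold form the peak; they need not be adjacent.
#' With no bin above threshold the peak is empty and every synchronization
#' index downstream is returned as 0.
#'
#' @param hist The experimental `correlogram`.
#' @param null A `shuffled_null` built from the same histogram.
#' @return A `peak_region` (possibly with zero bins).
#' @export
peak_zscore <- function(hist, null) {
  stopifnot(inherits(hist, "correlogram"), inherits(null, "shuffled_null"))
  if (null$n_samples != attr(hist, "n_intervals")) {
    stop("`null` was not built from this histogram", call. = FALSE)
  }
  bw <- attr(hist, "binwidth")
  tol <- bw * 1e-6
  test <- hist$bin_left >= -0.010 - tol & hist$bin_left < 0.010 - tol
  hit <- test & hist$count > null$threshold
  new_peak_region("zscore", hist, hist$bin_left[hit],
                  threshold = null$threshold,
                  expected_per_bin = null$threshold,
                  significant = any(hit), fallback = FALSE,
                  seed = null$seed)
}
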