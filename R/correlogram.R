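# Bin index of x under the half-open convention [left, left + bw) with 0 a
# left edge. The round() guard snaps values within ~1e-9 bins of an edge onto
# it: ms-grid timestamps stored as doubles can sit an ulp below the edge
# (e.g. 0.57/0.001 == 569.9999...).
bin_index <- function(x, binwidth) {
  as.integer(floor(round(x / binwidth, 9)))
}

new_correlogram <- function(bin_left, count, binwidth, n_intervals,
                            window = 0.1, baseline = c(0.06, 0.1)) {
  tol <- binwidth * 1e-6
  out <- tibble::tibble(bin_left = bin_left, count = as.integer(count))
  in_window <- bin_left >= -window - tol & bin_left <= window + tol
  in_baseline <-
    (bin_left >= -baseline[2] - tol & bin_left + binwidth <= -baseline[1] + tol) |
    (bin_left >= baseline[1] - tol & bin_left + binwidth <= baseline[2] + tol)
  if (!any(in_baseline)) {
    stop("no baseline bins: histogram does not cover the baseline region",
         call. = FALSE)
  }
  b <- out$count[in_baseline]
  structure(out,
            class = c("correlogram", class(out)),
            binwidth = binwidth,
            window = window,
            baseline_region = baseline,
            n_intervals = n_intervals,
            in_window = in_window,
            in_baseline = in_baseline,
            baseline_mean = mean(b),
            baseline_sd = sqrt(mean((b - mean(b))^2)))
}

#' Bin recurrence intervals into a cross-correlation histogram
#'
#' Intervals are discretized into contiguous half-open bins
#' `[left, left + binwidth)` with 0 as a bin left edge. The histogram
#' always covers at least the +/-100 ms analysis window (zero-padded if the
#' data are narrower) so that the baseline region — bins lying wholly
#' within +/-(60–100) ms — is well defined; intervals beyond the window are
#' retained in the histogram but excluded from baseline, cumulative-sum and
#' peak analysis. Baseline mean and population SD are stored as attributes
#' and reported by [baseline_stats()].
#'
#' @param intervals A numeric vector of signed intervals (seconds), or a
#'   tibble from [recurrence_intervals()] (its `interval` column is used,
#'   pooling all computed orders).
#' @param binwidth Bin width in seconds (default 0.001 s = 1 ms, the usual
#'   resolution for short-term synchronization).
#' @return A `correlogram`: a tibble with columns `bin_left` (s) and
#'   `count`, plus bin-geometry and baseline attributes.
#' @examples
#' h <- bin_intervals(c(-0.065, 0.015, -0.022, 0.045, -0.048, 0.008))
#' baseline_stats(h)
#' @export
bin_intervals <- function(intervals, binwidth = 0.001) {
  if (is.data.frame(intervals)) intervals <- intervals$interval
  if (length(intervals) == 0) stop("no intervals to bin", call. = FALSE)
  if (!is.numeric(intervals) || anyNA(intervals)) {
    stop("`intervals` must be numeric without missing values", call. = FALSE)
  }
  if (length(binwidth) != 1 || !is.finite(binwidth) || binwidth <= 0) {
    stop("`binwidth` must be a single positive number", call. = FALSE)
  }
  window <- 0.1
  k <- bin_index(intervals, binwidth)
  k_lo <- min(k, bin_index(-window, binwidth))
  k_hi <- max(k, bin_index(window, binwidth))
  counts <- tabulate(k - k_lo + 1L, nbins = k_hi - k_lo + 1L)
  new_correlogram(seq(k_lo, k_hi) * binwidth, counts, binwidth,
                  n_intervals = length(intervals), window = window)
}

#' Construct a correlogram from an already-binned table
#'
#' For histograms tabulated elsewhere (e.g. a published bin/frequency
#' table). Bins must be contiguous; the table is zero-padded to the
#' +/-100 ms analysis window if narrower.
#'
#' @param x A data frame with columns `bin_left` (seconds, ascending left
#'   edges) and `count`.
#' @param binwidth Bin width in seconds; inferred from consecutive edges
#'   when `NULL`.
#' @return A `correlogram` object.
#' @export
as_correlogram <- function(x, binwidth = NULL) {
  if (!is.data.frame(x) || !all(c("bin_left", "count") %in% names(x))) {
    stop("`x` must have columns `bin_left` and `count`", call. = FALSE)
  }
  x <- x[order(x$bin_left), ]
  if (is.null(binwidth)) {
    d <- diff(x$bin_left)
    if (length(d) == 0) stop("cannot infer `binwidth` from one bin", call. = FALSE)
    binwidth <- stats::median(d)
  }
  k <- bin_index(x$bin_left + binwidth / 2, binwidth)
  if (any(diff(k) != 1L)) stop("bins must be contiguous", call. = FALSE)
  if (any(x$count < 0)) stop("counts must be non-negative", call. = FALSE)
  window <- 0.1
  k_lo <- min(k, bin_index(-window, binwidth))
  k_hi <- max(k, bin_index(window, binwidth))
  counts <- integer(k_hi - k_lo + 1L)
  counts[k - k_lo + 1L] <- as.integer(x$count)
  new_correlogram(seq(k_lo, k_hi) * binwidth, counts, binwidth,
                  n_intervals = sum(x$count), window = window)
}

#' Baseline statistics of a correlogram
#'
#' The baseline region — bins wholly within +/-(60–100) ms — estimates the
#' chance-level bin count far from zero lag. The SD is the population SD
#' (divide by *n*), matching the significance formulas used downstream.
#'
#' @param hist A `correlogram`.
#' @return A one-row tibble: `baseline_mean`, `baseline_sd`, `n_bins`.
#' @export
baseline_stats <- function(hist) {
  stopifnot(inherits(hist, "correlogram"))
  tibble::tibble(
    baseline_mean = attr(hist, "baseline_mean"),
    baseline_sd = attr(hist, "baseline_sd"),
    n_bins = sum(attr(hist, "in_baseline"))
  )
}

window_bins <- function(hist) {
  w <- attr(hist, "in_window")
  tibble::tibble(bin_left = hist$bin_left[w], count = hist$count[w])
}

#' Normalized cumulative sum of a correlogram
#'
#' The baseline mean is subtracted from every bin count in the +/-100 ms
#' window, the differences are summed progressively from the left edge, and
#' each cumulative value is divided by the baseline mean. A synchronization
#' peak appears as a steep positive deflection near lag 0; the flat
#' portions reflect chance-level counts.
#'
#' @param hist A `correlogram` with positive baseline mean (a zero baseline
#'   means the recording is too short, or the bins too narrow, to estimate
#'   chance counts).
#' @return A tibble with columns `bin_left` and `cusum`.
#' @export
normalized_cumsum <- function(hist) {
  stopifnot(inherits(hist, "correlogram"))
  bm <- attr(hist, "baseline_mean")
  if (bm == 0) {
    stop(paste("baseline mean count is 0: record longer trains or use",
               "wider bins before computing the cumulative sum"), call. = FALSE)
  }
  w <- window_bins(hist)
  tibble::tibble(bin_left = w$bin_left, cusum = cumsum(w$count - bm) / bm)
}

#' Write a correlogram as a two-column CSV (`bin_left_s`, `count`)
#'
#' @param hist A `correlogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlogram <- function(hist, path) {
  stopifnot(inherits(hist, "correlogram"))
  readr::write_csv(
    tibble::tibble(bin_left_s = hist$bin_left, count = hist$count),
    path, progress = FALSE)
  invisible(path)
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf(
    "<correlogram> %d bins of %.4g s, %d intervals; baseline mean %.3g (sd %.3g)\n",
    nrow(x), attr(x, "binwidth"), attr(x, "n_intervals"),
    attr(x, "baseline_mean"), attr(x, "baseline_sd")))
  NextMethod()
}
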