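#' Synchronization indices from a correlogram peak
#'
#' Splits the peak into the counts expected by chance (the per-bin chance
#' count of the peak's method times the number of peak bins) and the
#' *extra* counts above them, then computes the six standard indices:
#'
#' * `cis` — extra counts per second of trial (common input strength,
#'   impulses/s), the index least influenced by discharge rate;
#' * `k_prime` — total peak counts over expected counts;
#' * `k_prime_minus_1` — extra counts over expected counts;
#' * `e_index` — extra counts per reference-unit discharge;
#' * `s_index` — extra counts per discharge of both units combined;
#' * `si` — extra counts over half the total counts in the +/-100 ms
#'   analysis window.
#'
#' Extra counts are floored at zero for the peak as a whole (per-bin
#' flooring would bias every index upward). An empty peak (z-score method,
#' no bin above threshold) yields all six indices equal to 0; a non-empty
#' peak whose counts do not exceed expectation yields `k_prime = 1` and 0
#' for the rest. Peak significance is the z-score of the mean peak count
#' against the baseline mean and SD (`NA` when the baseline SD is 0).
#'
#' @param hist A `correlogram`.
#' @param peak A `peak_region` computed on `hist`.
#' @param n_reference,n_event Discharge counts of the reference and event
#'   units.
#' @param trial_duration Trial duration in seconds (denominator of `cis`);
#'   conventionally the span over which both units are concurrently
#'   active.
#' @return A one-row tibble: `method`, the six indices,
#'   `peak_significance`, `peak_duration_s`, `peak_center_s`,
#'   `extra_counts`, `total_counts_in_peak`, `expected_counts_in_peak`,
#'   `trial_duration_s`.
#' @export
synch_indices <- function(hist, peak, n_reference, n_event, trial_duration) {
  stopifnot(inherits(hist, "correlogram"), inherits(peak, "peak_region"))
  if (!is.finite(trial_duration) || trial_duration <= 0) {
    stop("`trial_duration` must be positive", call. = FALSE)
  }
  bm <- attr(hist, "baseline_mean")
  bsd <- attr(hist, "baseline_sd")
  w <- window_bins(hist)
  window_total <- sum(w$count)

  if (peak$n_bins == 0) {
    total <- 0; expected <- 0; extra <- 0
    cis <- kp <- kp1 <- e <- s <- si <- 0
    significance <- 0
  } else {
    counts <- hist$count[match(peak$bin_lefts, hist$bin_left)]
    total <- sum(counts)
    expected <- peak$expected_per_bin * peak$n_bins
    if (expected == 0) {
      stop("expected peak counts are 0: baseline is degenerate", call. = FALSE)
    }
    extra <- max(0, total - expected)
    kp1 <- extra / expected
    kp <- 1 + kp1
    cis <- extra / trial_duration
    e <- extra / n_reference
    s <- extra / (n_reference + n_event)
    si <- extra / (window_total / 2)
    significance <- if (bsd == 0) NA_real_ else (mean(counts) - bm) / bsd
  }

  tibble::tibble(
    method = peak$method,
    cis = cis,
    k_prime = kp,
    k_prime_minus_1 = kp1,
    e_index = e,
    s_index = s,
    si = si,
    peak_significance = significance,
    peak_duration_s = peak$duration,
    peak_center_s = peak$center,
    extra_counts = extra,
    total_counts_in_peak = total,
    expected_counts_in_peak = expected,
    trial_duration_s = trial_duration
  )
}
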