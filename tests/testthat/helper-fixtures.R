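# Worked-example trains printed to six time points each.
printed_trains <- function() {
  list(motor_unit_1 = c(0.035, 0.115, 0.183, 0.250, 0.306, 0.377),
       motor_unit_2 = c(0.100, 0.205, 0.298, 0.377, 0.471, 0.577))
}

# Build an event tibble from two named numeric vectors of discharge times.
pair_events <- function(a, b, labels = c("a", "b")) {
  as_event_tbl(tibble::tibble(
    time = c(a, b),
    unit = rep(labels, c(length(a), length(b)))))
}

# Independent brute-force oracle for recurrence intervals: enumerate every
# pairwise difference per reference discharge, split by sign, and pick the
# k-th smallest magnitude per side. Shares no code with ri_pair().
oracle_intervals <- function(ref, ev, max_order) {
  rows <- list()
  for (t in ref) {
    d <- ev - t
    back <- sort(d[d < 0], decreasing = TRUE)   # nearest first
    fwd <- sort(d[d >= 0])                      # zero-lag tie is forward
    for (k in seq_len(max_order)) {
      if (length(back) >= k) {
        rows[[length(rows) + 1L]] <-
          tibble::tibble(order = k, reference_time = t,
                         side = "backward", interval = back[k])
      }
      if (length(fwd) >= k) {
        rows[[length(rows) + 1L]] <-
          tibble::tibble(order = k, reference_time = t,
                         side = "forward", interval = fwd[k])
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Sorted strictly-increasing random train on a millisecond-like grid.
random_train <- function(n, span = 2) {
  sort(sample(seq(0, span, by = 1e-3), n))
}

# Flat correlogram over +/-100 ms at 1 ms bins with selected bins replaced.
flat_correlogram <- function(base = 4, peak_lefts = numeric(0), peak_count = 10,
                             binwidth = 0.001) {
  lefts <- seq(-100, 100) * binwidth
  counts <- rep(base, length(lefts))
  counts[match(round(peak_lefts, 9), round(lefts, 9))] <- peak_count
  as_correlogram(tibble::tibble(bin_left = lefts, count = counts),
                 binwidth = binwidth)
}
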