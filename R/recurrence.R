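#' Assign reference and event roles to a pair of units
#'
#' The cross-correlation is anchored on the unit with fewer discharges (the
#' *reference*); the other unit supplies the latencies (the *event* unit).
#' With equal counts the unit appearing first in the table is the
#' reference, so the assignment does not depend on argument order beyond
#' that tie-break.
#'
#' @param events An event tibble containing exactly two units (or more, in
#'   which case `pair` selects two).
#' @param pair Optional character vector of two unit labels.
#' @return The [unit_characteristics()] tibble for the pair with an added
#'   `role` column (`"reference"` / `"event"`), reference row first.
#' @export
assign_reference <- function(events, pair = NULL) {
  events <- as_event_tbl(events)
  labs <- unit_labels(events)
  if (!is.null(pair)) {
    unknown <- setdiff(pair, labs)
    if (length(unknown) > 0) {
      stop(sprintf("unknown unit label(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    labs <- pair
  }
  if (length(labs) != 2) {
    stop("need exactly two units; use `pair` to select them", call. = FALSE)
  }
  trains <- discharge_times(events)[labs]
  n <- vapply(trains, length, 0L)
  if (any(n == 0)) {
    stop(sprintf("unit '%s' has no discharges", labs[n == 0][1]), call. = FALSE)
  }
  # single-discharge trains can still anchor a correlation; their ISI is NA
  chars <- tibble::tibble(
    unit = labs,
    n_discharges = unname(n),
    mean_isi = unname(vapply(trains, function(t) {
      if (length(t) >= 2) mean(diff(t)) else NA_real_
    }, 0)),
    isis = unname(lapply(trains, diff))
  )
  ref_first <- chars$n_discharges[1] <= chars$n_discharges[2]
  chars <- if (ref_first) chars else chars[2:1, ]
  chars$role <- c("reference", "event")
  chars
}

# k-th neighbour intervals for one reference train against one event train.
# base[i] = number of event times strictly before ref[i]; an event discharge
# exactly at the reference time is the order-1 *forward* neighbour (delta 0),
# never a backward one, so a physical coincidence is counted once.
ri_pair <- function(ref, ev, max_order) {
  base <- findInterval(ref, ev, left.open = TRUE)
  n_ev <- length(ev)
  rows <- vector("list", length(ref) * max_order)
  idx <- 0L
  for (i in seq_along(ref)) {
    t <- ref[i]
    for (k in seq_len(max_order)) {
      bi <- base[i] - k + 1L
      fi <- base[i] + k
      side <- character(0)
      iv <- double(0)
      if (bi >= 1L) {
        side <- "backward"
        iv <- ev[bi] - t
      }
      if (fi <= n_ev) {
        side <- c(side, "forward")
        iv <- c(iv, ev[fi] - t)
      }
      idx <- idx + 1L
      rows[[idx]] <- if (length(iv) > 0) {
        tibble::tibble(order = k, reference_time = t, side = side, interval = iv)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Multi-order recurrence intervals between two discharge trains
#'
#' For every reference discharge at time *t* and order *k*, the backward
#' interval is the latency to the *k*-th nearest event discharge strictly
#' before *t* (negative) and the forward interval the latency to the *k*-th
#' nearest event discharge at or after *t* (non-negative). Reference
#' discharges near the edges of the event train simply lack the missing
#' neighbour; no sentinel values are produced.
#'
#' @param events An event tibble with two units (see [assign_reference()]
#'   for the role assignment; override it with `reference`).
#' @param max_order Highest order of neighbour to compute (default 1; most
#'   synchronization analyses use first-order intervals only, since higher
#'   orders can introduce harmonic peaks at long latencies).
#' @param reference Optional unit label to force as reference.
#' @param pair Optional character vector of two unit labels to analyze.
#' @return A tibble with columns `order`, `reference_time`, `side`
#'   (`"backward"`/`"forward"`) and `interval` (signed seconds), ordered by
#'   reference discharge, then order, backward before forward. Attributes
#'   `reference_unit` and `event_unit` record the role assignment.
#' @examples
#' events <- as_event_tbl(data.frame(
#'   time = c(0.035, 0.115, 0.183, 0.250, 0.306, 0.377,
#'            0.100, 0.205, 0.298, 0.377, 0.471, 0.577),
#'   unit = rep(c("motor_unit_1", "motor_unit_2"), each = 6)))
#' recurrence_intervals(events)$interval
#' @export
recurrence_intervals <- function(events, max_order = 1, reference = NULL,
                                 pair = NULL) {
  if (length(max_order) != 1 || !is.finite(max_order) || max_order < 1) {
    stop("`max_order` must be a positive integer", call. = FALSE)
  }
  max_order <- as.integer(max_order)
  events <- as_event_tbl(events)
  roles <- assign_reference(events, pair = pair)
  if (!is.null(reference)) {
    if (!reference %in% roles$unit) {
      stop(sprintf("unknown reference unit '%s'", reference), call. = FALSE)
    }
    if (roles$unit[1] != reference) roles <- roles[2:1, ]
    roles$role <- c("reference", "event")
  }
  trains <- discharge_times(events)
  out <- ri_pair(trains[[roles$unit[1]]], trains[[roles$unit[2]]], max_order)
  out <- out[order(out$reference_time, out$order,
                   match(out$side, c("backward", "forward"))), ]
  attr(out, "reference_unit") <- roles$unit[1]
  attr(out, "event_unit") <- roles$unit[2]
  out
}
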