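#' Full time-domain synchronization analysis of a motor unit pair
#'
#' Runs the whole pipeline on an event table: role assignment (the unit
#' with fewer discharges becomes the reference), recurrence intervals up
#' to `order` (orders are pooled into one histogram; per-order intervals
#' are kept in the result), cross-correlation histogram, and, per
#' requested method, peak detection and the six synchronization indices.
#'
#' @param events An event tibble with two units (see [as_event_tbl()]), or
#'   more with `pair` selecting two.
#' @param methods Subset of `"visual"`, `"cumsum"`, `"zscore"`. The visual
#'   method is non-interactive: inspect [plot_cumsum()] output, then call
#'   again with `boundaries`.
#' @param order Highest recurrence-interval order (default 1).
#' @param binwidth Histogram bin width in seconds (default 0.001).
#' @param seed Integer seed; required when `"zscore"` is requested (its
#'   null is a single random realization).
#' @param trial_duration Trial duration in seconds for the CIS
#'   denominator. Default: the concurrent-activity span, from the later
#'   first discharge to the earlier last discharge of the two units.
#' @param boundaries Length-2 numeric `(left_s, right_s)` for the visual
#'   method.
#' @param reference Optional unit label forcing the reference role.
#' @param pair Optional character vector of two unit labels.
#' @return A `synch_analysis` object: list with `units` (characteristics +
#'   roles), `intervals`, `correlogram`, `cusum`, `peaks` (named list of
#'   `peak_region`), `indices` (tibble, one row per method) and `config`.
#'   Use [tidy()] for the indices, [glance()] for a one-row summary,
#'   [autoplot()] to plot.
#' @examples
#' pair <- simulate_pair(duration = 30, seed = 1)
#' fit <- synch_pair(pair$events, methods = c("cumsum", "zscore"), seed = 1)
#' tidy(fit)
#' @export
synch_pair <- function(events, methods = c("cumsum", "zscore"), order = 1,
                       binwidth = 0.001, seed = NULL, trial_duration = NULL,
                       boundaries = NULL, reference = NULL, pair = NULL) {
  methods <- match.arg(methods, c("visual", "cumsum", "zscore"),
                       several.ok = TRUE)
  if ("visual" %in% methods && is.null(boundaries)) {
    stop(paste("the visual method is non-interactive: inspect plot_cumsum()",
               "and supply `boundaries = c(left_s, right_s)`"), call. = FALSE)
  }
  if ("zscore" %in% methods && is.null(seed)) {
    stop("`seed` is required for the zscore method", call. = FALSE)
  }
  events <- as_event_tbl(events)
  intervals <- recurrence_intervals(events, max_order = order,
                                    reference = reference, pair = pair)
  ref_lab <- attr(intervals, "reference_unit")
  evt_lab <- attr(intervals, "event_unit")
  units <- unit_characteristics(events[events$unit %in% c(ref_lab, evt_lab), ])
  units <- units[match(c(ref_lab, evt_lab), units$unit), ]
  units$role <- c("reference", "event")

  trains <- discharge_times(events)
  overlap <- min(vapply(trains[c(ref_lab, evt_lab)], max, 0)) -
    max(vapply(trains[c(ref_lab, evt_lab)], min, 0))
  if (is.null(trial_duration)) trial_duration <- overlap
  if (!is.finite(trial_duration) || trial_duration <= 0) {
    stop("units are not concurrently active; supply `trial_duration`",
         call. = FALSE)
  }

  hist <- bin_intervals(intervals, binwidth = binwidth)
  cusum <- normalized_cumsum(hist)
  slower_isi <- max(units$mean_isi)

  peaks <- list()
  for (m in methods) {
    peaks[[m]] <- switch(m,
      visual = peak_manual(hist, boundaries[1], boundaries[2]),
      cumsum = peak_cumsum(hist),
      zscore = peak_zscore(hist, shuffled_null(hist, slower_isi, seed))
    )
  }
  indices <- dplyr::bind_rows(lapply(peaks, function(p) {
    synch_indices(hist, p,
                  n_reference = units$n_discharges[1],
                  n_event = units$n_discharges[2],
                  trial_duration = trial_duration)
  }))

  structure(
    list(units = units,
         intervals = intervals,
         correlogram = hist,
         cusum = cusum,
         peaks = peaks,
         indices = indices,
         config = list(methods = methods, order = order, binwidth = binwidth,
                       seed = seed, trial_duration = trial_duration,
                       overlap_duration = overlap, boundaries = boundaries,
                       reference = ref_lab, event = evt_lab,
                       version = as.character(utils::packageVersion("motorsync")))),
    class = "synch_analysis")
}

#' @export
print.synch_analysis <- function(x, ...) {
  u <- x$units
  cat(sprintf(
    "<synch_analysis> reference '%s' (%d discharges, mean ISI %.3f s) vs event '%s' (%d, %.3f s)\n",
    u$unit[1], u$n_discharges[1], u$mean_isi[1],
    u$unit[2], u$n_discharges[2], u$mean_isi[2]))
  cat(sprintf("  %d intervals (order <= %d), binwidth %g s, trial %.3g s\n",
              nrow(x$intervals), x$config$order, x$config$binwidth,
              x$config$trial_duration))
  print(x$indices[c("method", "cis", "k_prime", "e_index", "si",
                    "peak_duration_s", "peak_center_s")])
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-method synchronization indices
#'
#' @param x A `synch_analysis`.
#' @param ... Unused.
#' @return The indices tibble, one row per peak-detection method, with
#'   peak provenance columns (`significant`, `fallback`, `seed`).
#' @method tidy synch_analysis
#' @export
tidy.synch_analysis <- function(x, ...) {
  prov <- dplyr::bind_rows(lapply(x$peaks, function(p) {
    tibble::tibble(method = p$method, significant = p$significant,
                   fallback = p$fallback,
                   seed = if (is.null(p$seed)) NA_integer_ else p$seed)
  }))
  dplyr::left_join(x$indices, prov, by = "method")
}

#' One-row summary of a synchronization analysis
#'
#' @param x A `synch_analysis`.
#' @param ... Unused.
#' @return A one-row tibble: unit roles and characteristics, interval
#'   count, baseline statistics and trial duration.
#' @method glance synch_analysis
#' @export
glance.synch_analysis <- function(x, ...) {
  u <- x$units
  b <- baseline_stats(x$correlogram)
  tibble::tibble(
    reference = u$unit[1], event = u$unit[2],
    n_reference = u$n_discharges[1], n_event = u$n_discharges[2],
    mean_isi_reference = u$mean_isi[1], mean_isi_event = u$mean_isi[2],
    n_intervals = nrow(x$intervals),
    baseline_mean = b$baseline_mean, baseline_sd = b$baseline_sd,
    trial_duration_s = x$config$trial_duration
  )
}

#' Write a synchronization analysis report as JSON
#'
#' The report is schema-versioned and serialized deterministically: the
#' same input and seed produce a byte-identical file.
#'
#' @param x A `synch_analysis`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synch_report <- function(x, path) {
  stopifnot(inherits(x, "synch_analysis"))
  peaks <- lapply(x$peaks, function(p) {
    list(method = p$method,
         boundaries_s = p$boundaries,
         n_bins = p$n_bins,
         threshold = p$threshold,
         expected_per_bin = p$expected_per_bin,
         significant = p$significant,
         fallback = p$fallback,
         seed = p$seed)
  })
  units <- x$units
  units$isis <- NULL
  report <- list(
    schema_version = "1.0",
    config = x$config,
    units = units,
    indices = x$indices,
    peaks = peaks
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
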